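AA20 <- setdiff(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"), "X")

rand_peptide <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# symmetric diprotic reference table: pI of "GG" is (9.6 + 3.6) / 2 = 6.6
diprotic_table <- function() {
  custom_pka_table(c(C = 9, D = 4, E = 4.4, H = 6, K = 10, R = 12, Y = 10,
                     n_term = 9.6, c_term = 3.6), name = "diprotic-test")
}

# brute-force pI oracle: argmin |charge| over a fine pH grid
grid_pi <- function(seq, table = pka_table(), step = 1e-4) {
  grid <- seq(0, 14, by = step)
  q <- net_charge(seq, grid, table)
  grid[which.min(abs(q))]
}

# enumerate every global alignment of two short sequences (oracle for the
# affine-gap DP); returns the maximum achievable score
brute_force_align_score <- function(a, b, sub = blosum62(),
                                    gap_open = 11, gap_extend = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, col_a, col_b) {
    if (i > length(ca) && j > length(cb)) {
      s <- score_alignment(paste(col_a, collapse = ""),
                           paste(col_b, collapse = ""), sub,
                           gap_open, gap_extend)
      best <<- max(best, s)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      recurse(i + 1, j + 1, c(col_a, ca[i]), c(col_b, cb[j]))
    if (i <= length(ca))
      recurse(i + 1, j, c(col_a, ca[i]), c(col_b, "-"))
    if (j <= length(cb))
      recurse(i, j + 1, c(col_a, "-"), c(col_b, cb[j]))
  }
  recurse(1, 1, character(0), character(0))
  best
}

# random unrooted binary tree with positive branch lengths; returns the
# phylo object and its (additive) leaf distance matrix
random_additive_case <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE,
                   br = function(n) runif(n, 0.1, 2))
  d <- cophenetic(tr)
  list(tree = tr, d = d[sort(rownames(d)), sort(rownames(d))])
}

# least-squares fit of branch lengths for a fixed topology; returns RSS
topology_rss <- function(topo, d) {
  topo$edge.length <- rep(1, nrow(topo$edge))
  ne <- nrow(topo$edge)
  ids <- rownames(d)
  pairs <- t(combn(ids, 2))
  X <- matrix(0, nrow(pairs), ne)
  for (e in seq_len(ne)) {
    t2 <- topo
    t2$edge.length <- replace(rep(0, ne), e, 1)
    ce <- cophenetic(t2)
    X[, e] <- ce[pairs]
  }
  y <- d[pairs]
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

# brute-force topology search: best least-squares topology for a distance
# matrix over all unrooted binary topologies
best_ls_topology <- function(d) {
  ids <- rownames(d)
  topos <- phangorn::allTrees(length(ids), rooted = FALSE, tip.label = ids)
  rss <- vapply(topos, topology_rss, 0, d = d)
  topos[[which.min(rss)]]
}

small_generator_config <- function(n = 40L, seed = 7L) {
  generator_config(n_genes = n, seed = seed)
}
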