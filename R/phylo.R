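.pairwise_pdist <- function(seq_a, seq_b, substitution, gap_open, gap_extend) {
  al <- .align_global_cpp(seq_a, seq_b, substitution, gap_open, gap_extend)
  ca <- strsplit(al$aligned_a, "")[[1]]
  cb <- strsplit(al$aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both))
    stop("sequence pair with zero aligned (non-gap) columns")
  mean(ca[both] != cb[both])
}

.correct_dist <- function(p, correction) {
  if (correction == "p") return(p)
  cap <- 1 - exp(-10)
  ifelse(p >= cap, 10, -log(1 - p))
}

#' Pairwise evolutionary distances from global alignments
#'
#' Aligns every pair of sequences globally, computes the p-distance
#' (mismatch fraction over columns where neither sequence is gapped) and
#' optionally applies the Poisson multiple-hit correction
#' `d = -ln(1 - p)`, capped at 10 for saturated pairs.
#'
#' @param proteins a [protein_set] with at least 3 records.
#' @param correction `"poisson"` (default) or `"p"`.
#' @inheritParams align_global
#' @return Symmetric numeric matrix with zero diagonal and record ids as
#'   dimnames.
#' @export
distance_matrix <- function(proteins, correction = c("poisson", "p"),
                            substitution = blosum62(),
                            gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(proteins, "protein_set"), nrow(proteins) >= 3)
  correction <- match.arg(correction)
  n <- nrow(proteins)
  d <- matrix(0, n, n, dimnames = list(proteins$id, proteins$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- .pairwise_pdist(proteins$sequence[i], proteins$sequence[j],
                           substitution, gap_open, gap_extend)
      d[i, j] <- d[j, i] <- .correct_dist(p, correction)
    }
  }
  d
}

.fmt_bl <- function(x) sprintf("%.15g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining on the Q-criterion. Ties in the Q matrix are
#' broken deterministically by the lowest index pair (row-major order).
#' Negative branch lengths at a join are clamped to zero with the deficit
#' transferred to the sibling branch, preserving the path length between the
#' joined nodes. On an additive distance matrix the generating topology and
#' branch lengths are recovered exactly. The tree is returned unrooted, with
#' a basal trichotomy.
#'
#' @param d symmetric numeric matrix with zero diagonal, taxon ids as
#'   dimnames, at least 3 taxa.
#' @return An [ape::read.tree] `phylo` object.
#' @examples
#' d <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' nj_tree(d)
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs taxon dimnames")
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE)))
    stop("distance matrix is not symmetric")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")

  labels <- rownames(d)
  clusters <- labels  # newick fragments
  D <- unname(d)
  while (length(clusters) > 3) {
    m <- nrow(D)
    R <- rowSums(D)
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * D[i, j] - R[i] - R[j]
        if (q < best) { best <- q; bi <- i; bj <- j }
      }
    }
    li <- D[bi, bj] / 2 + (R[bi] - R[bj]) / (2 * (m - 2))
    lj <- D[bi, bj] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    if (li < 0) li <- 0  # both-negative degenerate case
    newc <- sprintf("(%s:%s,%s:%s)", clusters[bi], .fmt_bl(li),
                    clusters[bj], .fmt_bl(lj))
    keep <- setdiff(seq_len(m), c(bi, bj))
    dnew <- (D[bi, keep] + D[bj, keep] - D[bi, bj]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    clusters <- c(clusters[keep], newc)
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l <- pmax(0, c((d12 + d13 - d23) / 2,
                 (d12 + d23 - d13) / 2,
                 (d13 + d23 - d12) / 2))
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 clusters[1], .fmt_bl(l[1]),
                 clusters[2], .fmt_bl(l[2]),
                 clusters[3], .fmt_bl(l[3]))
  ape::read.tree(text = txt)
}

.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

#' Assign a query leaf to a reference class by clade placement
#'
#' Replays the visual clade-reading step of reference-based phylogenetic
#' classification: the tree is rooted at the panel's outgroup (midpoint
#' rooting when no outgroup is present), the query's sister group is
#' collected, and the query is assigned the majority class of that sister
#' group when the majority exceeds one half. If the immediate sister group
#' is tied, the search widens one node toward the root and retries once;
#' otherwise the query is `"unresolved"`. An S-RNase screen uses the
#' resulting label as a veto: placement inside the Class-I or Class-II
#' RNase-T2 clades rejects a candidate.
#'
#' @param tree a `phylo` object whose tips are the query plus panel members.
#' @param query_id tip label of the query.
#' @param panel a [reference_panel] labelling every non-query tip.
#' @return An object of class `clade_assignment`: `query_id`,
#'   `assigned_class` (a panel label or `"unresolved"`), `sister_labels`
#'   (class counts in the sister group used) and `support_fraction`.
#' @export
assign_clade <- function(tree, query_id, panel) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!query_id %in% tree$tip.label) stop("query '", query_id,
                                          "' is not a leaf of the tree")
  labels <- panel$labels
  others <- setdiff(tree$tip.label, query_id)
  miss <- setdiff(others, names(labels))
  if (length(miss)) stop("unlabelled tree leaves: ",
                         paste(miss, collapse = ", "))

  og <- intersect(others, names(labels)[labels == "outgroup"])
  tree <- if (length(og)) {
    out_tips <- if (length(og) > 1 &&
                    ape::is.monophyletic(tree, og)) og else sort(og)[1]
    ape::root(tree, outgroup = out_tips, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tree)
  }

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  qtip <- which(tree$tip.label == query_id)
  parent_of <- function(node) {
    e <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(e)) e[1] else NA_integer_
  }
  node <- parent_of(qtip)
  majority <- function(node) {
    sis <- setdiff(.tips_under(tree, node), query_id)
    if (!length(sis)) return(NULL)
    tab <- table(labels[sis])
    list(tab = tab, frac = max(tab) / sum(tab),
         class = names(tab)[which.max(tab)])
  }
  for (attempt in 1:2) {
    if (is.na(node)) break
    res <- majority(node)
    if (!is.null(res) && res$frac > 0.5) {
      return(structure(list(query_id = query_id, assigned_class = res$class,
                            sister_labels = res$tab,
                            support_fraction = unname(res$frac)),
                       class = "clade_assignment"))
    }
    node <- parent_of(node)
  }
  last <- if (!is.na(node)) majority(node) else res
  structure(list(query_id = query_id, assigned_class = "unresolved",
                 sister_labels = if (is.null(last)) table(character(0)) else last$tab,
                 support_fraction = if (is.null(last)) 0 else unname(last$frac)),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat(sprintf("query %s -> %s (support %.2f)\n", x$query_id,
              x$assigned_class, x$support_fraction))
  invisible(x)
}

#' Place one query against a labelled reference panel
#'
#' Convenience wrapper: builds the distance matrix over the query plus all
#' panel members (a precomputed panel-only matrix may be supplied to avoid
#' recomputing panel pairs), infers the neighbor-joining tree and assigns
#' the query's clade.
#'
#' @param query sequence string or single-record [protein_set].
#' @param query_id leaf label for the query.
#' @param panel a [reference_panel].
#' @param panel_dist optional precomputed symmetric matrix of panel-member
#'   distances (dimnames = panel ids), as produced by [distance_matrix].
#' @inheritParams distance_matrix
#' @return A list with the `clade_assignment` and the `phylo` tree.
#' @export
place_query <- function(query, query_id, panel, panel_dist = NULL,
                        correction = c("poisson", "p"),
                        substitution = blosum62(),
                        gap_open = 11, gap_extend = 1) {
  correction <- match.arg(correction)
  qseq <- .as_sequence(query)
  ids <- panel$proteins$id
  if (query_id %in% ids) stop("query id collides with a panel id")
  if (is.null(panel_dist))
    panel_dist <- distance_matrix(panel$proteins, correction,
                                  substitution, gap_open, gap_extend)
  qd <- vapply(panel$proteins$sequence, function(r)
    .correct_dist(.pairwise_pdist(qseq, r, substitution, gap_open,
                                  gap_extend), correction), 0,
    USE.NAMES = FALSE)
  n <- length(ids) + 1L
  d <- matrix(0, n, n, dimnames = list(c(query_id, ids), c(query_id, ids)))
  d[ids, ids] <- panel_dist[ids, ids]
  d[query_id, ids] <- d[ids, query_id] <- qd
  tree <- nj_tree(d)
  list(assignment = assign_clade(tree, query_id, panel), tree = tree)
}
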