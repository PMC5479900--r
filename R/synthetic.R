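.AA20 <- setdiff(.AA_LETTERS, "X")
# typical globular-protein residue frequencies used as the background model
.AA_FREQ <- c(A = .083, C = .014, D = .054, E = .062, F = .039, G = .072,
              H = .022, I = .053, K = .058, L = .091, M = .022, N = .043,
              P = .052, Q = .040, R = .051, S = .068, T = .059, V = .066,
              W = .011, Y = .030)

#' Configuration of the synthetic-dataset generator
#'
#' Defines the composition and statistical structure of a labelled synthetic
#' screening dataset: a proteome containing planted S-RNase-like genes
#' (S-lineage diagnostic site, basic pI, 1-2 introns, style-restricted
#' expression), S-like RNase-T2 genes (pattern 4 present, acidic pI, broad
#' expression), SSK1-like genes (type-I length, WAFE-variant C-terminus,
#' pollen-restricted expression), broadly expressed SKP1 genes with decoy
#' C-termini, long chimeric type-II SKP1 genes, and unrelated background
#' genes; matched gene models, a raw-count expression matrix over
#' leaf/pollen/style, a labelled reference panel, and a ground-truth table.
#'
#' @param n_genes total number of genes (default 200).
#' @param fractions named class fractions summing to 1; default 10%
#'   planted_srnase, 15% s_like_rnase, 5% ssk1_like, 10% skp1_broad,
#'   5% skp1_type2, 55% background.
#' @param pi_band_srnase,pi_band_slike target pI bands (defaults `[8, 10]`
#'   and `[4.5, 7]`).
#' @param mutation_rate per-residue substitution rate applied to family
#'   seeds when deriving genes (default 0.18) and panel references
#'   (`ref_mutation_rate`, default 0.12).
#' @param ref_mutation_rate see `mutation_rate`.
#' @param expression_means named list of per-class mean FPKM over
#'   (leaf, pollen, style).
#' @param sigma lognormal noise s.d. on the FPKM scale (default 0.3).
#' @param seed RNG seed; the same configuration and seed always yield the
#'   identical dataset, byte for byte.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_genes = 200L,
                             fractions = c(planted_srnase = 0.10,
                                           s_like_rnase = 0.15,
                                           ssk1_like = 0.05,
                                           skp1_broad = 0.10,
                                           skp1_type2 = 0.05,
                                           background = 0.55),
                             pi_band_srnase = c(8, 10),
                             pi_band_slike = c(4.5, 7),
                             mutation_rate = 0.18,
                             ref_mutation_rate = 0.12,
                             expression_means = list(
                               planted_srnase = c(leaf = 0.05, pollen = 0.05,
                                                  style = 60),
                               s_like_rnase = c(leaf = 20, pollen = 15,
                                                style = 10),
                               ssk1_like = c(leaf = 0.05, pollen = 45,
                                             style = 0.05),
                               skp1_broad = c(leaf = 12, pollen = 30,
                                              style = 8),
                               skp1_type2 = c(leaf = 0.05, pollen = 30,
                                              style = 0.05),
                               background = c(leaf = 10, pollen = 8,
                                              style = 12)),
                             sigma = 0.3,
                             seed = 42L) {
  stopifnot(n_genes >= 10, abs(sum(fractions) - 1) < 1e-8,
            all(fractions >= 0), sigma >= 0,
            pi_band_srnase[1] < pi_band_srnase[2],
            pi_band_slike[1] < pi_band_slike[2])
  need <- c("planted_srnase", "s_like_rnase", "ssk1_like", "skp1_broad",
            "skp1_type2", "background")
  stopifnot(setequal(names(fractions), need),
            setequal(names(expression_means), need))
  structure(list(n_genes = as.integer(n_genes), fractions = fractions[need],
                 pi_band_srnase = pi_band_srnase,
                 pi_band_slike = pi_band_slike,
                 mutation_rate = mutation_rate,
                 ref_mutation_rate = ref_mutation_rate,
                 expression_means = expression_means[need],
                 sigma = sigma, seed = as.integer(seed)),
            class = "generator_config")
}

.random_seq <- function(len) {
  paste(sample(.AA20, len, replace = TRUE, prob = .AA_FREQ), collapse = "")
}

.mutate_seq <- function(seq, rate, protect = integer(0)) {
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) s[i] <- sample(setdiff(.AA20, s[i]), 1)
  paste(s, collapse = "")
}

.implant <- function(seq, pos, motif) {
  paste0(substr(seq, 1, pos - 1), motif,
         substr(seq, pos + nchar(motif), nchar(seq)))
}

# remove every anchor match except the one planted at `keep_pos` (NA = all)
.strip_anchors <- function(seq, anchor_regex, keep_pos = NA) {
  m <- gregexpr(anchor_regex, seq, perl = TRUE)[[1]]
  if (m[1] < 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  for (p in as.integer(m)) {
    if (!is.na(keep_pos) && p == keep_pos) next
    s[p] <- "Q"  # breaks the K of the anchor without adding charge groups
  }
  paste(s, collapse = "")
}

# remove spurious WAF occurrences in the C-terminal window except the
# planted one starting at `keep_pos`
.strip_waf <- function(seq, window, keep_pos = NA) {
  n <- nchar(seq)
  offset <- max(0L, n - window)
  m <- gregexpr("WAF", substr(seq, offset + 1L, n), fixed = TRUE)[[1]]
  if (m[1] < 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  for (p in offset + as.integer(m)) {
    if (!is.na(keep_pos) && p == keep_pos) next
    s[p] <- "S"
  }
  paste(s, collapse = "")
}

# mutate/swap steps can occasionally create a spurious conserved-site
# anchor, and stripping one can nudge the pI; alternate until both the
# leftmost-anchor position and the pI band hold
.finalize_rnase <- function(seq, band, protect, anchor_re, anchor_pos,
                            table = pka_table()) {
  for (round in 1:10) {
    seq <- .strip_anchors(seq, anchor_re, anchor_pos)
    seq <- .adjust_pi(seq, band, protect, table)
    first <- regexpr(anchor_re, seq, perl = TRUE)
    pI <- isoelectric_point(seq, table)$pI
    if (as.integer(first) == anchor_pos && pI >= band[1] && pI <= band[2])
      return(seq)
  }
  stop("could not jointly satisfy anchor placement and pI band")
}

# greedy composition adjustment: swap acidic<->basic residues at unprotected
# positions until the computed pI enters [band[1], band[2]]
.adjust_pi <- function(seq, band, protect = integer(0), table = pka_table()) {
  s <- strsplit(seq, "")[[1]]
  free <- setdiff(seq_along(s), protect)
  max_iter <- 10L * length(s)
  for (iter in seq_len(max_iter)) {
    pI <- isoelectric_point(paste(s, collapse = ""), table)$pI
    if (pI >= band[1] && pI <= band[2])
      return(paste(s, collapse = ""))
    if (pI < band[1]) {
      cand <- free[s[free] %in% c("D", "E")]
      if (!length(cand)) cand <- free[!s[free] %in% c("K", "R", "H")]
      if (!length(cand)) break
      s[sample(cand, 1)] <- sample(c("K", "R"), 1)
    } else {
      cand <- free[s[free] %in% c("K", "R")]
      if (!length(cand)) cand <- free[!s[free] %in% c("D", "E")]
      if (!length(cand)) break
      s[sample(cand, 1)] <- sample(c("D", "E"), 1)
    }
  }
  stop("unattainable pI band [", band[1], ", ", band[2],
       "] for this sequence length; widen the band")
}

# split a transcript of `tx_len` nt into `n_exons` exons separated by 100-nt
# introns, starting at genomic coordinate `start`
.make_exons <- function(start, tx_len, n_exons) {
  base <- tx_len %/% n_exons
  sizes <- rep(base, n_exons)
  sizes[n_exons] <- sizes[n_exons] + tx_len - sum(sizes)
  starts <- start + cumsum(c(0, sizes[-n_exons] + 100L))
  cbind(start = starts, end = starts + sizes - 1L)
}

#' Generate a labelled synthetic screening dataset
#'
#' Builds the full input bundle the screening pipeline consumes, with known
#' ground truth. Sequences are drawn from a background residue model;
#' class-specific features (conserved-site anchors and diagnostic sites,
#' C-terminal motifs, pI bands enforced by greedy acidic/basic residue
#' swapping, intron counts, tissue-restricted expression profiles) are
#' planted on top, and family membership is created by mutating shared seed
#' sequences so that homology and clade placement behave like a real gene
#' family. Raw counts are derived by inverting the FPKM formula around the
#' class mean profiles, so FPKM normalisation is exercised end to end. No
#' real biological sequence is emitted.
#'
#' Generated features are verified with the package's own extractors
#' (pattern scanner, pI, C-terminal analysis); the generator fails rather
#' than emit a gene violating its declared truth.
#'
#' @param cfg a [generator_config].
#' @param dir optional directory; when given, all files consumed by
#'   [run_pipeline] are written there (`proteome.fasta`, `genes.gff3`,
#'   `counts.tsv`, `lengths.tsv`, `library_sizes.tsv`, `panel.fasta`,
#'   `panel_labels.tsv`, `truth.tsv`).
#' @return A list with `proteome` ([protein_set]), `gene_models`,
#'   `expression` (counts [expression_matrix]), `panel`
#'   ([reference_panel]), `truth` (data frame) and, when `dir` was given,
#'   `paths`.
#' @export
generate_dataset <- function(cfg = generator_config(), dir = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  anchor_re <- "KHG[ST]"
  pkt <- pka_table()

  counts_per_class <- {
    k <- floor(cfg$fractions * cfg$n_genes)
    k[1] <- k[1] + cfg$n_genes - sum(k)
    k
  }

  # family seed sequences (shared ancestry within each reference class)
  seed_len_rnase <- 220L
  anchor_pos <- 61L
  srnase_seed <- .adjust_pi(
    .strip_anchors(.implant(.random_seq(seed_len_rnase), anchor_pos,
                            "KHGSCGSAA"), anchor_re, anchor_pos),
    mean(cfg$pi_band_srnase) + c(-0.5, 0.5),
    protect = anchor_pos:(anchor_pos + 8L))
  class1_seed <- .strip_anchors(.implant(.random_seq(seed_len_rnase),
                                         anchor_pos, "KHGTRASTG"),
                                anchor_re, anchor_pos)
  class2_seed <- .strip_anchors(.implant(.random_seq(seed_len_rnase),
                                         anchor_pos, "KHGTRGSTA"),
                                anchor_re, anchor_pos)
  outgroup_seed <- .strip_anchors(.implant(.random_seq(seed_len_rnase),
                                           anchor_pos, "KHGSGASTA"),
                                  anchor_re, anchor_pos)
  ssk1_seed <- local({
    s <- .random_seq(170L)
    s <- .implant(s, nchar(s) - 8L, "WAFEGVDED")
    .strip_waf(s, 25L, keep_pos = nchar(s) - 8L)
  })
  skp1_seed <- local({
    s <- .random_seq(172L)
    s <- .implant(s, nchar(s) - 8L, "WAFEGAKED")
    .strip_waf(s, 25L, keep_pos = nchar(s) - 8L)
  })

  rnase_protect <- anchor_pos:(anchor_pos + 8L)
  make_refs <- function(seed, n, prefix, protect) {
    protos <- vapply(seq_len(n), function(i)
      .mutate_seq(seed, cfg$ref_mutation_rate, protect), "")
    setNames(protos, sprintf("%s%d", prefix, seq_len(n)))
  }
  refs <- c(make_refs(srnase_seed, 4, "REF_SRNASE_", rnase_protect),
            make_refs(class1_seed, 4, "REF_CLASS1_", rnase_protect),
            make_refs(class2_seed, 3, "REF_CLASS2_", rnase_protect),
            make_refs(outgroup_seed, 2, "REF_OUTGRP_", rnase_protect),
            make_refs(ssk1_seed, 4, "REF_SSK1_", 162:170),
            make_refs(skp1_seed, 4, "REF_SKP1_", 164:172))
  ref_labels <- c(rep("S-RNase", 4), rep("Class-I", 4), rep("Class-II", 3),
                  rep("outgroup", 2), rep("SSK1", 4), rep("SKP1-other", 4))
  names(ref_labels) <- names(refs)
  panel <- reference_panel(protein_set(names(refs), unname(refs)),
                           ref_labels)

  classes <- rep(names(counts_per_class), counts_per_class)
  n <- length(classes)
  ids <- sprintf("G%03d", seq_len(n))

  sequences <- character(n)
  introns <- integer(n)
  motif_texts <- character(n)
  pattern4 <- logical(n)
  true_pi <- rep(NA_real_, n)
  profiles <- character(n)

  for (k in seq_len(n)) {
    cl <- classes[k]
    if (cl == "planted_srnase") {
      s <- .mutate_seq(srnase_seed, cfg$mutation_rate, rnase_protect)
      s <- .finalize_rnase(s, cfg$pi_band_srnase, rnase_protect,
                           anchor_re, anchor_pos, pkt)
      sequences[k] <- s
      introns[k] <- sample(1:2, 1)
      motif_texts[k] <- "CGS"
      pattern4[k] <- FALSE
      true_pi[k] <- isoelectric_point(s, pkt)$pI
      profiles[k] <- "style-specific"
    } else if (cl == "s_like_rnase") {
      s <- .mutate_seq(class1_seed, cfg$mutation_rate, rnase_protect)
      s <- .finalize_rnase(s, cfg$pi_band_slike, rnase_protect,
                           anchor_re, anchor_pos, pkt)
      sequences[k] <- s
      introns[k] <- sample(4:7, 1)
      motif_texts[k] <- "R"
      pattern4[k] <- TRUE
      true_pi[k] <- isoelectric_point(s, pkt)$pI
      profiles[k] <- "broad"
    } else if (cl == "ssk1_like") {
      s <- .mutate_seq(ssk1_seed, cfg$mutation_rate, 162:170)
      variant <- sample(c("canonical", "wafge"), 1)
      cterm <- if (variant == "canonical") "WAFEGVDED" else {
        tail_len <- sample(5:9, 1)
        paste0("WAFGE", paste(sample(c("A", "G", "S", "T", "V", "P"),
                                     tail_len - 1, replace = TRUE),
                              collapse = ""), "D")
      }
      s <- paste0(substr(s, 1, nchar(s) - nchar(cterm)), cterm)
      s <- .strip_waf(s, 25L, keep_pos = nchar(s) - nchar(cterm) + 1L)
      sequences[k] <- s
      introns[k] <- sample(0:2, 1)
      motif_texts[k] <- if (variant == "canonical") "WAFE" else "WAFGE"
      profiles[k] <- "pollen-specific"
    } else if (cl == "skp1_broad") {
      s <- .mutate_seq(skp1_seed, cfg$mutation_rate, 164:172)
      cterm <- sample(c("WAFEGAKED", "WAFDLICL", "WAFEPQQ"), 1)
      s <- paste0(substr(s, 1, nchar(s) - nchar(cterm)), cterm)
      s <- .strip_waf(s, 25L, keep_pos = nchar(s) - nchar(cterm) + 1L)
      sequences[k] <- s
      introns[k] <- sample(0:2, 1)
      motif_texts[k] <- substr(cterm, 1, 5)
      profiles[k] <- "broad"
    } else if (cl == "skp1_type2") {
      s <- paste0(.mutate_seq(skp1_seed, cfg$mutation_rate, 164:172),
                  .random_seq(sample(130:230, 1)))
      s <- paste0(substr(s, 1, nchar(s) - 9L), "WAFEGVDED")
      s <- .strip_waf(s, 25L, keep_pos = nchar(s) - 8L)
      sequences[k] <- s
      introns[k] <- sample(0:3, 1)
      motif_texts[k] <- "WAFE"
      profiles[k] <- "pollen-specific"
    } else {  # background
      s <- .strip_anchors(.random_seq(sample(150:400, 1)), anchor_re)
      sequences[k] <- s
      introns[k] <- sample(0:8, 1)
      motif_texts[k] <- ""
      profiles[k] <- "broad"
    }
  }

  # self-consistency: verify planted features with the pipeline's extractors
  for (k in seq_len(n)) {
    cl <- classes[k]
    if (cl %in% c("planted_srnase", "s_like_rnase")) {
      lin <- classify_rnase_lineage(scan_patterns(sequences[k]))
      want <- if (pattern4[k]) "s_like" else "s_lineage_compatible"
      if (lin != want)
        stop("generator self-check failed for ", ids[k], ": lineage ", lin)
    }
    if (cl == "ssk1_like" &&
        !analyze_skp1_cterm(sequences[k])$ssk1_consistent)
      stop("generator self-check failed for ", ids[k], ": C-terminus")
  }

  proteome <- protein_set(ids, sequences, species = "synthetic",
                          source = "genome", gene_id = ids)

  # gene models realising the planted intron counts
  tx_len <- 3L * nchar(sequences) + 3L
  gstart <- cumsum(c(1L, utils::head(tx_len + 100L * introns + 500L, -1)))
  gene_models <- setNames(lapply(seq_len(n), function(k)
    gene_model(ids[k],
               list(.make_exons(gstart[k], tx_len[k], introns[k] + 1L)))),
    ids)

  # expression: lognormal noise around class mean FPKM, inverted to counts
  tissues <- c("leaf", "pollen", "style")
  lib_sizes <- setNames(round(runif(3, 1.5e7, 2.5e7)), tissues)
  fpkm_target <- t(vapply(classes, function(cl)
    cfg$expression_means[[cl]][tissues], numeric(3)))
  noise <- matrix(rlnorm(n * 3, 0, cfg$sigma), n, 3)
  fpkm <- fpkm_target * noise
  counts <- round(fpkm * outer(tx_len, lib_sizes) / 1e9)
  dimnames(counts) <- list(ids, tissues)
  expression <- expression_matrix(counts, "counts",
                                  lengths = setNames(tx_len, ids),
                                  library_sizes = lib_sizes)

  truth <- data.frame(gene_id = ids, class = classes,
                      true_pi = round(true_pi, 3),
                      pattern4_present = pattern4,
                      motif_text = motif_texts,
                      intron_count = introns,
                      tissue_profile = profiles,
                      stringsAsFactors = FALSE)

  out <- list(proteome = proteome, gene_models = gene_models,
              expression = expression, panel = panel, truth = truth,
              config = cfg)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    write_fasta(proteome, p("proteome.fasta"))
    write_fasta(panel$proteins, p("panel.fasta"))
    write.table(data.frame(id = names(panel$labels),
                           class = unname(panel$labels)),
                p("panel_labels.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    .write_gff3(gene_models, p("genes.gff3"))
    write_expression(expression, p("counts.tsv"))
    write.table(data.frame(gene_id = ids, length = tx_len), p("lengths.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(tissue = tissues,
                           library_size = unname(lib_sizes)),
                p("library_sizes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- setNames(
      vapply(c("proteome.fasta", "genes.gff3", "counts.tsv", "lengths.tsv",
               "library_sizes.tsv", "panel.fasta", "panel_labels.tsv",
               "truth.tsv"), p, ""),
      c("proteome", "gff", "counts", "lengths", "library_sizes",
        "panel", "panel_labels", "truth"))
  }
  out
}

.write_gff3 <- function(gene_models, path) {
  grl <- lapply(names(gene_models), function(gid) {
    gm <- gene_models[[gid]]
    ex <- gm$mrnas[[1]]
    span <- c(min(ex[, 1]), max(ex[, 2]))
    mid <- paste0(gid, ".t1")
    g <- GenomicRanges::GRanges(
      "chr1",
      IRanges::IRanges(c(span[1], span[1], ex[, 1]),
                       c(span[2], span[2], ex[, 2])),
      strand = gm$strand)
    g$type <- c("gene", "mRNA", rep("exon", nrow(ex)))
    g$ID <- c(gid, mid, paste0(mid, ".exon", seq_len(nrow(ex))))
    g$Parent <- IRanges::CharacterList(
      c(list(character(0)), list(gid), rep(list(mid), nrow(ex))))
    g
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Evaluate screen verdicts against the generator's ground truth
#'
#' A planted S-RNase counts as a true positive when the S-RNase screen calls
#' it `candidate`; likewise planted SSK1-like genes for the SSK1 screen.
#' Everything else in the dataset is a true negative for that screen.
#'
#' @param result a `screen_result` from [screen_srnase] or [screen_ssk1]
#'   (or its verdict data frame).
#' @param truth the truth table from [generate_dataset].
#' @param positive_class truth class counted as positive; defaults to
#'   `"planted_srnase"` or `"ssk1_like"` according to the screen's role.
#' @return A list with `sensitivity`, `specificity`, `precision` and the
#'   2x2 `confusion` table.
#' @export
evaluate_recovery <- function(result, truth, positive_class = NULL) {
  verdicts <- if (inherits(result, "screen_result")) result$verdicts
              else result
  if (is.null(positive_class)) {
    role <- verdicts$role[1]
    positive_class <- if (identical(role, "ssk1_screen")) "ssk1_like"
                      else "planted_srnase"
  }
  sym <- c(setdiff(verdicts$gene_id, truth$gene_id),
           setdiff(truth$gene_id, verdicts$gene_id))
  if (length(sym))
    stop("verdicts and truth cover different gene sets: ",
         paste(sym, collapse = ", "))
  truth <- truth[match(verdicts$gene_id, truth$gene_id), ]
  is_pos <- truth$class == positive_class
  called <- verdicts$final == "candidate"
  tp <- sum(is_pos & called); fn <- sum(is_pos & !called)
  fp <- sum(!is_pos & called); tn <- sum(!is_pos & !called)
  confusion <- matrix(c(tp, fp, fn, tn), 2, 2,
                      dimnames = list(truth = c("positive", "negative"),
                                      called = c("candidate", "other")))
  list(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp) tp / (tp + fp) else NA_real_,
       confusion = confusion)
}
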