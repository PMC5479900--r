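#' FPKM normalisation of a raw-count expression matrix
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM(g, t) = C(g, t) * 1e9 / (N(t) * L(g))` where `C` is the raw fragment
#' count, `N` the total mapped fragments of the tissue's library and `L` the
#' transcript length in nt (the longest transcript of a multi-isoform gene is
#' the conventional choice). The result is invariant to jointly rescaling all
#' counts and library sizes.
#'
#' @param em an [expression_matrix] with `unit = "counts"`.
#' @return An [expression_matrix] with `unit = "FPKM"`.
#' @examples
#' em <- expression_matrix(matrix(100, 1, 1, dimnames = list("g", "t")),
#'                         "counts", lengths = c(g = 1000),
#'                         library_sizes = c(t = 1e6))
#' compute_fpkm(em)$values  # 100
#' @export
compute_fpkm <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "counts") stop("compute_fpkm requires unit = 'counts'")
  L <- em$lengths[rownames(em$values)]
  N <- em$library_sizes[colnames(em$values)]
  fpkm <- em$values * 1e9 / outer(L, N)
  expression_matrix(fpkm, "FPKM", lengths = em$lengths,
                    library_sizes = em$library_sizes)
}

#' Average replicate columns of an expression matrix
#'
#' Collapses replicate libraries to one column per tissue before specificity
#' calling. FPKM replicates are averaged; count replicates are summed along
#' with their library sizes (the count-scale analogue of averaging).
#'
#' @param em an [expression_matrix].
#' @param groups character vector mapping each column to a tissue label; by
#'   default a trailing `_r<k>` or `_rep<k>` suffix is stripped.
#' @return An [expression_matrix] with one column per tissue, tissue order
#'   following first appearance.
#' @export
average_replicates <- function(em, groups = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  cols <- colnames(em$values)
  if (is.null(groups)) groups <- sub("_r(ep)?[0-9]+$", "", cols)
  stopifnot(length(groups) == length(cols))
  tissues <- unique(groups)
  agg <- function(f) {
    out <- vapply(tissues, function(t)
      apply(em$values[, groups == t, drop = FALSE], 1, f),
      numeric(nrow(em$values)))
    matrix(out, nrow = nrow(em$values),
           dimnames = list(rownames(em$values), tissues))
  }
  if (em$unit == "FPKM")
    return(expression_matrix(agg(mean), "FPKM"))
  v <- agg(sum)
  N <- vapply(tissues, function(t)
    sum(em$library_sizes[cols[groups == t]]), 0)
  expression_matrix(v, "counts", lengths = em$lengths, library_sizes = N)
}

#' Call per-gene tissue specificity from an FPKM matrix
#'
#' Each gene/tissue value is classified with a two-threshold scheme:
#' `expressed` at or above `expressed_min`, `absent` at or below
#' `absent_max`, `ambiguous` in between (ambiguous values count as evidence
#' of expression when rejecting specificity claims - the conservative
#' direction for a screen). A gene is `specific_to` a tissue when exactly
#' that tissue is expressed and every other assayed tissue is absent; it is
#' `broad` when at least two tissues are expressed.
#'
#' @param em an [expression_matrix] with `unit = "FPKM"`.
#' @param expressed_min FPKM at or above which a gene counts as expressed
#'   (default 1.0).
#' @param absent_max FPKM at or below which a gene counts as absent
#'   (default 0.5).
#' @return A data frame of class `specificity_calls`: `gene_id`, one status
#'   column per tissue, `specific_to` (NA when none) and `broad`.
#' @examples
#' m <- matrix(c(0, 0, 50), 1, dimnames = list("g", c("leaf", "pollen", "style")))
#' call_specificity(expression_matrix(m, "FPKM"))
#' @export
call_specificity <- function(em, expressed_min = 1.0, absent_max = 0.5) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "FPKM") stop("call_specificity requires unit = 'FPKM'")
  if (!(expressed_min >= absent_max && absent_max >= 0))
    stop("need expressed_min >= absent_max >= 0")
  v <- em$values
  status <- matrix("ambiguous", nrow(v), ncol(v), dimnames = dimnames(v))
  status[v >= expressed_min] <- "expressed"
  status[v <= absent_max] <- "absent"
  expressed_n <- rowSums(status == "expressed")
  absent_n <- rowSums(status == "absent")
  specific <- ifelse(expressed_n == 1 & absent_n == ncol(v) - 1,
                     colnames(v)[apply(status == "expressed", 1,
                                       function(r) which(r)[1])],
                     NA_character_)
  out <- data.frame(gene_id = rownames(v), status,
                    specific_to = specific, broad = expressed_n >= 2,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  class(out) <- c("specificity_calls", "data.frame")
  attr(out, "tissues") <- colnames(v)
  attr(out, "thresholds") <- c(expressed_min = expressed_min,
                               absent_max = absent_max)
  out
}
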