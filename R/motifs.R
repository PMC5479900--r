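.as_sequence <- function(x) {
  if (inherits(x, "protein_set")) {
    stopifnot(nrow(x) == 1)
    return(x$sequence)
  }
  stopifnot(is.character(x), length(x) == 1)
  toupper(x)
}

#' Define an anchored amino-acid pattern
#'
#' Patterns are data, not code: each spec names an anchor regular expression
#' that locates a conserved region (by default the second conserved
#' active-site histidine motif of the RNase-T2 family), an offset window
#' relative to the anchor's end, and a site regular expression evaluated
#' inside that window. Polarity records what a hit means: pattern 4 (an
#' arginine at the diagnostic site) marks S-like, non-S-lineage RNase-T2
#' genes, while the CGS/CSS alternatives are compatible with the S-RNase
#' lineage.
#'
#' @param name unique spec name (e.g. `"pattern4"`).
#' @param site_regex regular expression evaluated inside the window.
#' @param anchor_regex regular expression locating the conserved region.
#' @param offset_window integer pair: first and last residue offset after the
#'   anchor's end (1 = first residue after the anchor).
#' @param polarity `"s_like_indicative"` or `"s_lineage_indicative"`.
#' @param provisional logical; marks literature slots whose residue
#'   definitions are placeholders awaiting curation.
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(name, site_regex, anchor_regex = "KHG[ST]",
                         offset_window = c(1L, 5L),
                         polarity = c("s_like_indicative",
                                      "s_lineage_indicative"),
                         provisional = FALSE) {
  polarity <- match.arg(polarity)
  stopifnot(length(offset_window) == 2,
            offset_window[1] <= offset_window[2], offset_window[1] >= 1)
  # regexes must compile
  tryCatch({regexpr(anchor_regex, "A"); regexpr(site_regex, "A")},
           error = function(e) stop("malformed pattern spec '", name, "': ",
                                    conditionMessage(e)))
  structure(list(name = name, anchor_regex = anchor_regex,
                 offset_window = as.integer(offset_window),
                 site_regex = site_regex, polarity = polarity,
                 provisional = provisional),
            class = "pattern_spec")
}

#' Default RNase-T2 pattern specs
#'
#' The shipped defaults define the diagnostic site used for S-lineage
#' screening: `pattern4` (`R` in the window after the conserved active-site
#' anchor, found only in non-S-lineage proteins) and the S-lineage-compatible
#' alternatives `cgs` and `css`. Slots for patterns 1-3 are present but
#' provisional.
#'
#' @param anchor_regex anchor shared by all default specs.
#' @return Named list of [pattern_spec] objects.
#' @export
default_rnase_patterns <- function(anchor_regex = "KHG[ST]") {
  specs <- list(
    pattern_spec("pattern4", "R", anchor_regex,
                 polarity = "s_like_indicative"),
    pattern_spec("cgs", "CGS", anchor_regex,
                 polarity = "s_lineage_indicative"),
    pattern_spec("css", "CSS", anchor_regex,
                 polarity = "s_lineage_indicative"),
    pattern_spec("pattern1", "[FLIV]", anchor_regex,
                 polarity = "s_lineage_indicative", provisional = TRUE),
    pattern_spec("pattern2", "[NQ]", anchor_regex,
                 polarity = "s_lineage_indicative", provisional = TRUE),
    pattern_spec("pattern3", "[GA]", anchor_regex,
                 polarity = "s_like_indicative", provisional = TRUE))
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names(specs))) stop("duplicate spec names")
  specs
}

#' Scan a sequence against anchored pattern specs
#'
#' The anchor is located as the leftmost match of `anchor_regex`; the site
#' regex is then evaluated inside the offset window relative to the anchor's
#' end. If the anchor is absent the hit is indeterminate (the diagnostic
#' site cannot be located), never a negative.
#'
#' @param x an amino-acid string or single-record [protein_set].
#' @param specs list of [pattern_spec] objects (default
#'   [default_rnase_patterns()]).
#' @return Data frame with one row per spec: `spec_name`, `found`,
#'   `anchor_position` (0-based start of the anchor), `matched_text`,
#'   `indeterminate`, `polarity`.
#' @examples
#' scan_patterns("MAAKHGSCGSAA")
#' @export
scan_patterns <- function(x, specs = default_rnase_patterns()) {
  seq <- .as_sequence(x)
  stopifnot(length(specs) >= 1)
  rows <- lapply(specs, function(sp) {
    m <- regexpr(sp$anchor_regex, seq, perl = TRUE)
    if (m < 0) {
      return(data.frame(spec_name = sp$name, found = FALSE,
                        anchor_position = NA_integer_,
                        matched_text = NA_character_, indeterminate = TRUE,
                        polarity = sp$polarity, stringsAsFactors = FALSE))
    }
    anchor_end <- as.integer(m) + attr(m, "match.length") - 1L
    w <- substr(seq, anchor_end + sp$offset_window[1],
                min(nchar(seq), anchor_end + sp$offset_window[2]))
    sm <- regexpr(sp$site_regex, w, perl = TRUE)
    found <- !is.na(sm) && sm > 0 && nzchar(w)
    data.frame(
      spec_name = sp$name, found = found,
      anchor_position = as.integer(m) - 1L,
      matched_text = if (found) regmatches(w, sm) else NA_character_,
      indeterminate = FALSE, polarity = sp$polarity,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("pattern_hits", "data.frame")
  out
}

#' Classify RNase-T2 lineage from pattern hits
#'
#' Pattern 4 is found only in proteins encoded by non-S-lineage RNase-T2
#' genes, so its determinate absence is compatible with the S-RNase lineage
#' (screening criterion: pattern 4 absent). An absent anchor makes the call
#' indeterminate.
#'
#' @param hits result of [scan_patterns] with the default spec set.
#' @return `"s_like"`, `"s_lineage_compatible"` or `"indeterminate"`.
#' @export
classify_rnase_lineage <- function(hits) {
  h <- hits[hits$spec_name == "pattern4", , drop = FALSE]
  if (nrow(h) != 1) stop("hits must contain exactly one 'pattern4' entry")
  if (h$indeterminate) "indeterminate"
  else if (h$found) "s_like"
  else "s_lineage_compatible"
}

#' Classify a SKP1-family protein as type I or II
#'
#' Angiosperm SKP1-like genes fall into two types; type II proteins are much
#' longer chimeric proteins and are excluded from SSK1 candidacy. Typical
#' SKP1 proteins are ~150-190 residues, so the default length threshold is
#' 250 (strict inequality: a protein exactly at the threshold is type I).
#'
#' @param x sequence string or single-record [protein_set].
#' @param length_threshold residue count above which a protein is type II.
#' @return `"I"` or `"II"`.
#' @export
classify_skp1_type <- function(x, length_threshold = 250L) {
  stopifnot(length_threshold > 0)
  if (nchar(.as_sequence(x)) > length_threshold) "II" else "I"
}

#' Analyse the C-terminus of a SKP1-family protein
#'
#' SSK1 adapters carry a diagnostic C-terminus: the conventional `WAFE`
#' motif (with observed variants such as `WAFGE` and `WAFAE`, in which one
#' or more residues are inserted between the phenylalanine and the acidic
#' residue) followed by a short 5-9 residue tail whose last residue is
#' always D. The motif grammar is `W-A-F-x{0,3}-[DE]`, matched leftmost
#' within the final `window` residues; if `WAF` occurs with no acidic
#' residue within three positions the literal continuation is reported as a
#' non-canonical, non-acidic motif (e.g. `WAFDLICL`-style decoys fail the
#' terminal-acidity rule instead). `ssk1_consistent` requires a type-I
#' protein, an acidic motif, a 5-9 residue tail, and a terminal D (or E when
#' `allow_E_terminal`). The `GVDED` tail conserved in Rosaceae SSK1s is
#' flagged but not required.
#'
#' @param x sequence string or single-record [protein_set].
#' @param window number of C-terminal residues searched (default 25,
#'   minimum 10).
#' @param length_threshold passed to [classify_skp1_type].
#' @param allow_E_terminal accept a terminal E as well as D.
#' @return An object of class `skp_motif_report`.
#' @examples
#' analyze_skp1_cterm(paste0(strrep("A", 150), "WAFEGVDED"))
#' @export
analyze_skp1_cterm <- function(x, window = 25L, length_threshold = 250L,
                               allow_E_terminal = FALSE) {
  stopifnot(window >= 10)
  seq <- .as_sequence(x)
  type <- classify_skp1_type(seq, length_threshold)
  n <- nchar(seq)
  offset <- max(0L, n - as.integer(window))  # residues before the window
  tailseq <- substr(seq, offset + 1L, n)
  final_res <- substr(seq, n, n)
  terminal_ok <- final_res == "D" || (allow_E_terminal && final_res == "E")

  rep0 <- list(motif_found = FALSE, motif_text = "", motif_is_canonical = FALSE,
               inserted_residues = "", tail = "", tail_length = 0L,
               tail_ends_in_D = final_res == "D", gvded_present = FALSE,
               type = type, ssk1_consistent = FALSE)

  m <- regexpr("WAF.{0,3}?[DE]", tailseq, perl = TRUE)
  acidic_found <- m > 0
  if (!acidic_found) {
    w <- regexpr("WAF", tailseq, fixed = TRUE)
    if (w < 0) {
      out <- rep0
    } else {
      # WAF present but no acidic residue within 3 positions: report the
      # literal continuation, trimmed at the protein end
      start <- offset + as.integer(w)
      motif <- substr(seq, start, min(n, start + 7L))
      tail <- substr(seq, start + nchar(motif), n)
      out <- rep0
      out$motif_found <- TRUE
      out$motif_text <- motif
      out$tail <- tail
      out$tail_length <- nchar(tail)
      out$gvded_present <- grepl("GVDED", tailseq, fixed = TRUE)
    }
  } else {
    motif <- regmatches(tailseq, m)
    start <- offset + as.integer(m)
    tail <- substr(seq, start + nchar(motif), n)
    out <- list(
      motif_found = TRUE,
      motif_text = motif,
      motif_is_canonical = startsWith(motif, "WAFE"),
      inserted_residues = substr(motif, 4, nchar(motif) - 1),
      tail = tail,
      tail_length = nchar(tail),
      tail_ends_in_D = final_res == "D",
      gvded_present = grepl("GVDED", tailseq, fixed = TRUE),
      type = type,
      ssk1_consistent = type == "I" && nchar(tail) >= 5 &&
        nchar(tail) <= 9 && terminal_ok)
  }
  structure(out, class = "skp_motif_report")
}

#' @export
print.skp_motif_report <- function(x, ...) {
  cat(sprintf("SKP1 C-terminal report: motif %s%s, tail '%s' (%d aa), type %s\n",
              if (x$motif_found) sprintf("'%s'", x$motif_text) else "absent",
              if (x$motif_is_canonical) " (canonical)" else "",
              x$tail, x$tail_length, x$type))
  cat(sprintf("  GVDED: %s | SSK1-consistent: %s\n",
              x$gvded_present, x$ssk1_consistent))
  invisible(x)
}
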