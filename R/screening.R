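#' Screening configuration
#'
#' All thresholds and labels used by the S-RNase and SSK1 screens, exposed as
#' plain data so a run's decisions are fully auditable. The defaults encode
#' the standard screening rules: S-RNases are basic proteins (pI above 7.5),
#' carry at most two introns, lack amino-acid pattern 4, are similar at the
#' amino-acid level to known S-RNases, and are mainly expressed in the style.
#'
#' @param ip_threshold pI above which criterion 3 passes (default 7.5).
#' @param max_introns maximum intron count (default 2).
#' @param homology_gate minimum self-normalised alignment score against the
#'   reference panel (default 0.25).
#' @param pistil_tissue_label,pollen_tissue_label,leaf_tissue_label tissue
#'   labels used by the expression criteria.
#' @param expressed_min,absent_max FPKM thresholds for [call_specificity].
#' @param stringency `"strict"` requires style-specific expression
#'   (pollen-specific for the SSK1 screen); `"permissive"` only requires
#'   expression in the focal tissue and absence in leaf, accommodating
#'   S-RNases with low stigma/style expression.
#' @param pka_table_name name passed to [pka_table].
#' @param anchor_regex anchor for [default_rnase_patterns].
#' @param skp1_length_threshold type-II length cutoff (default 250).
#' @param skp1_window C-terminal search window (default 25).
#' @param allow_E_terminal accept terminal E as well as D in the SSK1 tail
#'   rule.
#' @param gap_open,gap_extend,correction alignment and distance settings.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(ip_threshold = 7.5,
                          max_introns = 2L,
                          homology_gate = 0.25,
                          pistil_tissue_label = "style",
                          pollen_tissue_label = "pollen",
                          leaf_tissue_label = "leaf",
                          expressed_min = 1.0,
                          absent_max = 0.5,
                          stringency = c("strict", "permissive"),
                          pka_table_name = "expasy-bjellqvist-like",
                          anchor_regex = "KHG[ST]",
                          skp1_length_threshold = 250L,
                          skp1_window = 25L,
                          allow_E_terminal = FALSE,
                          gap_open = 11,
                          gap_extend = 1,
                          correction = "poisson") {
  stringency <- match.arg(stringency)
  stopifnot(ip_threshold >= 0, ip_threshold <= 14, max_introns >= 0,
            homology_gate >= 0, homology_gate <= 1,
            expressed_min >= absent_max, absent_max >= 0,
            skp1_length_threshold > 0, skp1_window >= 10)
  structure(list(
    ip_threshold = ip_threshold, max_introns = as.integer(max_introns),
    homology_gate = homology_gate,
    pistil_tissue_label = pistil_tissue_label,
    pollen_tissue_label = pollen_tissue_label,
    leaf_tissue_label = leaf_tissue_label,
    expressed_min = expressed_min, absent_max = absent_max,
    stringency = stringency, pka_table_name = pka_table_name,
    anchor_regex = anchor_regex,
    skp1_length_threshold = as.integer(skp1_length_threshold),
    skp1_window = as.integer(skp1_window),
    allow_E_terminal = allow_E_terminal,
    gap_open = gap_open, gap_extend = gap_extend,
    correction = correction), class = "screen_config")
}

#' Read / write a screening configuration as YAML
#'
#' Round-trips losslessly: `read_screen_config(write_screen_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param path YAML file path.
#' @return For `read_screen_config`, a [screen_config].
#' @export
read_screen_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(screen_config, vals)
}

#' @param cfg a [screen_config].
#' @rdname read_screen_config
#' @export
write_screen_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "screen_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# expression criterion for one gene; returns list(flag, detail)
.expression_flag <- function(calls, id, focal, leaf, stringency) {
  if (is.null(calls) || !id %in% calls$gene_id)
    return(list(flag = "unknown", detail = NA_character_))
  row <- calls[calls$gene_id == id, , drop = FALSE]
  tissues <- attr(calls, "tissues")
  if (!focal %in% tissues || !leaf %in% tissues)
    return(list(flag = "unknown", detail = NA_character_))
  ok <- if (stringency == "strict") {
    identical(row$specific_to, focal)
  } else {
    row[[focal]] != "absent" && row[[leaf]] == "absent"
  }
  list(flag = if (isTRUE(ok)) "pass" else "fail",
       detail = if (is.na(row$specific_to)) {
         if (row$broad) "broad" else "none"
       } else row$specific_to)
}

.prep_expression <- function(expr) {
  if (is.null(expr)) return(NULL)
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$unit == "counts") expr <- compute_fpkm(expr)
  expr
}

#' Screen genes for S-RNase candidacy
#'
#' The decision engine combining the four S-RNase criteria per gene:
#' (1) amino-acid similarity to the reference panel's RNase-T2 classes at or
#' above the homology gate; (2) amino-acid pattern 4 determinately absent;
#' (3) isoelectric point above the threshold; (4) style-restricted
#' expression; plus the intron rule (at most `max_introns` when a gene model
#' is available) and a clade veto: placement inside the Class-I or Class-II
#' RNase-T2 clades rejects. Missing evidence (no gene model, no expression
#' row) yields `"unknown"`, never `"fail"`; a gene whose available criteria
#' all pass but with unknowns is `"inconclusive"`, listed for follow-up
#' rather than accepted or discarded.
#'
#' @param records a [protein_set] of query proteins.
#' @param panel a [reference_panel] containing S-RNase, Class-I, Class-II
#'   (and ideally outgroup) references.
#' @param gene_models optional named list of [gene_model] objects (keyed by
#'   gene id or record id).
#' @param expr optional [expression_matrix] (counts are converted to FPKM).
#' @param cfg a [screen_config].
#' @return An object of class `screen_result`: a verdict table with one row
#'   per gene (criterion flags in `{pass, fail, unknown}`, clade assignment,
#'   final call in `{candidate, rejected, inconclusive}`, reasons) plus the
#'   measured features (pI, homology score, intron count, lineage,
#'   expression call).
#' @export
screen_srnase <- function(records, panel, gene_models = NULL, expr = NULL,
                          cfg = screen_config()) {
  stopifnot(inherits(records, "protein_set"), inherits(panel, "reference_panel"))
  if (nrow(records) == 0) stop("empty record set")
  expr <- .prep_expression(expr)
  calls <- if (!is.null(expr))
    call_specificity(expr, cfg$expressed_min, cfg$absent_max) else NULL
  pkt <- pka_table(cfg$pka_table_name)
  specs <- default_rnase_patterns(cfg$anchor_regex)
  panel_dist <- distance_matrix(panel$proteins, cfg$correction,
                                gap_open = cfg$gap_open,
                                gap_extend = cfg$gap_extend)
  family_classes <- c("S-RNase", "Class-I", "Class-II")

  rows <- lapply(seq_len(nrow(records)), function(k) {
    id <- records$id[k]
    seq <- records$sequence[k]
    reasons <- character(0)

    hs <- homology_score(seq, panel, class_filter = family_classes,
                         gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
    homology_ok <- if (hs >= cfg$homology_gate) "pass" else "fail"
    if (homology_ok == "fail")
      reasons <- c(reasons, sprintf(
        "criterion 1: homology score %.3f below gate %.2f", hs,
        cfg$homology_gate))

    lineage <- classify_rnase_lineage(scan_patterns(seq, specs))
    pattern4_absent <- switch(lineage, s_like = "fail",
                              s_lineage_compatible = "pass",
                              indeterminate = "unknown")
    if (pattern4_absent == "fail")
      reasons <- c(reasons, "criterion 2: amino-acid pattern 4 present (S-like lineage)")

    pI <- isoelectric_point(seq, pkt)$pI
    ip_ok <- if (pI > cfg$ip_threshold) "pass" else "fail"
    if (ip_ok == "fail")
      reasons <- c(reasons, sprintf("criterion 3: pI %.2f not above %.2f",
                                    pI, cfg$ip_threshold))

    gm_key <- if (!is.na(records$gene_id[k])) records$gene_id[k] else id
    model <- gene_models[[gm_key]]
    n_introns <- if (!is.null(model)) intron_count(model) else NA_integer_
    introns_ok <- if (is.null(model)) "unknown"
      else if (n_introns <= cfg$max_introns) "pass" else "fail"
    if (introns_ok == "fail")
      reasons <- c(reasons, sprintf("intron rule: %d introns exceed %d",
                                    n_introns, cfg$max_introns))

    ef <- .expression_flag(calls, id, cfg$pistil_tissue_label,
                           cfg$leaf_tissue_label, cfg$stringency)
    if (ef$flag == "fail")
      reasons <- c(reasons, sprintf(
        "criterion 4: no style-restricted expression (profile: %s)",
        ef$detail))

    pl <- place_query(seq, id, panel, panel_dist,
                      correction = cfg$correction,
                      gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)
    clade <- pl$assignment$assigned_class
    if (clade %in% c("Class-I", "Class-II"))
      reasons <- c(reasons, sprintf(
        "clade veto: placed in %s RNase-T2 clade", clade))

    flags <- c(homology_ok, pattern4_absent, ip_ok, introns_ok, ef$flag)
    final <- if (any(flags == "fail") || clade %in% c("Class-I", "Class-II"))
      "rejected"
    else if (any(flags == "unknown")) "inconclusive"
    else "candidate"

    data.frame(gene_id = id, role = "srnase_screen",
               homology_ok = homology_ok, pattern4_absent = pattern4_absent,
               ip_ok = ip_ok, introns_ok = introns_ok,
               expression_ok = ef$flag,
               homology = hs, lineage = lineage, pI = pI,
               intron_count = n_introns,
               expression_profile = ef$detail,
               clade = clade,
               clade_support = pl$assignment$support_fraction,
               final = final,
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(verdicts = verdicts, config = cfg, role = "srnase_screen"),
            class = "screen_result")
}

#' Screen genes for SSK1 candidacy
#'
#' SSK1 adapters are the diagnostic marker of S-RNase-based GSI on the
#' pollen side: type-I SKP1-like proteins with the C-terminal WAFE-variant
#' motif and pollen-restricted expression. Type-II (long, chimeric) proteins
#' are excluded outright; the GVDED tail is reported but not required. Clade
#' placement against an SSK1/SKP1 panel is reported as supporting evidence.
#'
#' @inheritParams screen_srnase
#' @param panel a [reference_panel] with SSK1 and SKP1-other references.
#' @return An object of class `screen_result`.
#' @export
screen_ssk1 <- function(records, panel, expr = NULL, cfg = screen_config()) {
  stopifnot(inherits(records, "protein_set"), inherits(panel, "reference_panel"))
  if (nrow(records) == 0) stop("empty record set")
  expr <- .prep_expression(expr)
  calls <- if (!is.null(expr))
    call_specificity(expr, cfg$expressed_min, cfg$absent_max) else NULL
  panel_dist <- distance_matrix(panel$proteins, cfg$correction,
                                gap_open = cfg$gap_open,
                                gap_extend = cfg$gap_extend)

  rows <- lapply(seq_len(nrow(records)), function(k) {
    id <- records$id[k]
    seq <- records$sequence[k]
    reasons <- character(0)

    rep <- analyze_skp1_cterm(seq, window = cfg$skp1_window,
                              length_threshold = cfg$skp1_length_threshold,
                              allow_E_terminal = cfg$allow_E_terminal)
    type_ok <- if (rep$type == "I") "pass" else "fail"
    if (type_ok == "fail")
      reasons <- c(reasons, "type II (chimeric) SKP1-like protein excluded")
    motif_ok <- if (rep$motif_found) "pass" else "fail"
    if (motif_ok == "fail")
      reasons <- c(reasons, "no WAFE-variant C-terminal motif found")

    ef <- .expression_flag(calls, id, cfg$pollen_tissue_label,
                           cfg$leaf_tissue_label, cfg$stringency)
    if (ef$flag == "fail")
      reasons <- c(reasons, sprintf(
        "no pollen-restricted expression (profile: %s)", ef$detail))

    pl <- place_query(seq, id, panel, panel_dist,
                      correction = cfg$correction,
                      gap_open = cfg$gap_open, gap_extend = cfg$gap_extend)

    flags <- c(type_ok, motif_ok, ef$flag)
    final <- if (any(flags == "fail")) "rejected"
    else if (any(flags == "unknown")) "inconclusive"
    else "candidate"

    data.frame(gene_id = id, role = "ssk1_screen",
               type = rep$type, type_ok = type_ok,
               motif_ok = motif_ok, motif_text = rep$motif_text,
               motif_is_canonical = rep$motif_is_canonical,
               tail = rep$tail, tail_length = rep$tail_length,
               gvded_present = rep$gvded_present,
               ssk1_consistent = rep$ssk1_consistent,
               expression_ok = ef$flag,
               expression_profile = ef$detail,
               clade = pl$assignment$assigned_class,
               clade_support = pl$assignment$support_fraction,
               final = final,
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(verdicts = verdicts, config = cfg, role = "ssk1_screen"),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  tab <- table(factor(x$verdicts$final,
                      levels = c("candidate", "inconclusive", "rejected")))
  cat(sprintf("%s: %d gene(s) screened\n", x$role, nrow(x$verdicts)))
  print(tab)
  cand <- x$verdicts$gene_id[x$verdicts$final == "candidate"]
  if (length(cand)) cat("candidates:", paste(cand, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  v <- object$verdicts
  flag_cols <- intersect(c("homology_ok", "pattern4_absent", "ip_ok",
                           "introns_ok", "type_ok", "motif_ok",
                           "expression_ok"), names(v))
  list(role = object$role,
       n = nrow(v),
       final = table(v$final),
       criteria = lapply(setNames(flag_cols, flag_cols),
                         function(cl) table(v[[cl]])))
}

#' Run the full screening pipeline from input files
#'
#' Reads a proteome FASTA, an optional GFF3 of gene models, an optional
#' expression table (raw counts are FPKM-normalised), and a labelled
#' reference panel; runs the S-RNase screen against the panel's RNase-T2
#' classes and the SSK1 screen against its SKP1 classes; and writes the
#' report bundle to `out_dir`: verdict TSVs, a per-gene feature table,
#' Newick trees of the panel plus any surviving (candidate or inconclusive)
#' genes, a run log recording every threshold, and a machine-readable JSON
#' summary of final-class counts. Outputs carry no timestamps, so reruns
#' with identical inputs and configuration are byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param proteome path to the query protein FASTA, or a [protein_set].
#' @param panel_fasta,panel_labels paths defining the reference panel, or a
#'   [reference_panel] passed as `panel_fasta` (with `panel_labels` omitted).
#' @param gff optional GFF3 path or named list of [gene_model]s.
#' @param expression optional counts/FPKM TSV path or [expression_matrix].
#' @param lengths,library_sizes companion TSV paths when `expression` is a
#'   counts TSV.
#' @param unit unit of the expression table when read from file.
#' @param config a [screen_config], or a path to its YAML form.
#' @return Invisibly, a list with both [screen_srnase] / [screen_ssk1]
#'   results, the feature table and the summary counts.
#' @export
run_pipeline <- function(out_dir, proteome, panel_fasta, panel_labels = NULL,
                         gff = NULL, expression = NULL, lengths = NULL,
                         library_sizes = NULL, unit = "counts",
                         config = screen_config()) {
  if (is.character(config)) config <- read_screen_config(config)
  records <- if (inherits(proteome, "protein_set")) proteome
             else read_fasta(proteome)
  panel <- if (inherits(panel_fasta, "reference_panel")) panel_fasta
           else read_panel(panel_fasta, panel_labels)
  models <- if (is.null(gff) || is.list(gff)) gff else read_gene_models(gff)
  expr <- if (is.null(expression) || inherits(expression, "expression_matrix"))
    expression
  else read_expression(expression, unit, lengths, library_sizes)
  expr <- .prep_expression(expr)

  keep <- function(classes) {
    ids <- names(panel$labels)[panel$labels %in% classes]
    reference_panel(panel$proteins[panel$proteins$id %in% ids, ],
                    panel$labels[ids])
  }
  rnase_panel <- keep(c("S-RNase", "Class-I", "Class-II", "outgroup"))
  skp_panel <- keep(c("SSK1", "SKP1-other"))

  sr <- screen_srnase(records, rnase_panel, models, expr, config)
  sk <- screen_ssk1(records, skp_panel, expr, config)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) write.table(df, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(sr$verdicts, "verdicts_srnase.tsv")
  wt(sk$verdicts, "verdicts_ssk1.tsv")

  features <- data.frame(
    id = sr$verdicts$gene_id,
    length = nchar(records$sequence),
    pI = round(sr$verdicts$pI, 2),
    lineage = sr$verdicts$lineage,
    intron_count = sr$verdicts$intron_count,
    rnase_clade = sr$verdicts$clade,
    skp1_type = sk$verdicts$type,
    skp1_motif = sk$verdicts$motif_text,
    expression_profile = sr$verdicts$expression_profile,
    location = records$location,
    high_x_flag = records$flag_high_x,
    stringsAsFactors = FALSE)
  wt(features, "features.tsv")

  survivors <- function(res, pan) {
    ids <- res$verdicts$gene_id[res$verdicts$final != "rejected"]
    sub <- records[records$id %in% ids, , drop = FALSE]
    all <- protein_set(c(sub$id, pan$proteins$id),
                       c(sub$sequence, pan$proteins$sequence))
    nj_tree(distance_matrix(all, config$correction,
                            gap_open = config$gap_open,
                            gap_extend = config$gap_extend))
  }
  ape::write.tree(survivors(sr, rnase_panel),
                  file.path(out_dir, "tree_srnase.nwk"))
  ape::write.tree(survivors(sk, skp_panel),
                  file.path(out_dir, "tree_ssk1.nwk"))

  write_screen_config(config, file.path(out_dir, "run_config.yaml"))
  counts_of <- function(res) as.list(table(factor(
    res$verdicts$final, levels = c("candidate", "inconclusive", "rejected"))))
  summary_counts <- list(srnase_screen = counts_of(sr),
                         ssk1_screen = counts_of(sk))
  jsonlite::write_json(summary_counts, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(srnase = sr, ssk1 = sk, features = features,
                 summary = summary_counts))
}
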