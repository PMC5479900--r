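#' @importFrom methods as is
NULL

.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Construct a set of protein records
#'
#' The central sequence container of the package: one row per protein, with
#' identity, species, tissue provenance, origin (genome or transcriptome) and
#' an optional link to a gene model. Sequences are amino-acid strings over the
#' 20-letter alphabet plus `X`; letters are normalised to upper case. `X`
#' residues are tolerated but carry no charge and match no pattern downstream;
#' records with more than 10% `X` are flagged in the `flag_high_x` column.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param species optional character vector of species names.
#' @param tissues optional character vector; comma-separated tissue labels in
#'   which the protein was observed (may be empty for genome-derived entries).
#' @param source `"genome"` or `"transcriptome"`, recycled.
#' @param gene_id optional character vector linking records to gene models.
#' @param location optional opaque location string (e.g. a scaffold name).
#' @return A data frame of class `protein_set`.
#' @examples
#' protein_set("p1", "MKVLAG", tissues = "style")
#' @export
protein_set <- function(id, sequence, species = NA_character_,
                        tissues = "", source = "genome",
                        gene_id = NA_character_, location = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("id and sequence must have equal length")
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for id(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  bad <- regexpr(sprintf("[^%s]", paste(.AA_LETTERS, collapse = "")), sequence)
  if (any(bad > 0)) {
    k <- which(bad > 0)[1]
    stop(sprintf("invalid residue '%s' at position %d in record '%s'",
                 substr(sequence[k], bad[k], bad[k]), bad[k], id[k]))
  }
  source <- rep_len(as.character(source), length(id))
  if (!all(source %in% c("genome", "transcriptome")))
    stop("source must be 'genome' or 'transcriptome'")
  x_frac <- vapply(strsplit(sequence, ""), function(s) mean(s == "X"), 0)
  out <- data.frame(
    id = id, sequence = sequence,
    species = rep_len(as.character(species), length(id)),
    tissues = rep_len(as.character(tissues), length(id)),
    source = source,
    gene_id = rep_len(as.character(gene_id), length(id)),
    location = rep_len(as.character(location), length(id)),
    flag_high_x = x_frac > 0.10,
    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

.parse_fasta_header <- function(header) {
  parts <- strsplit(trimws(header), "\\s+")[[1]]
  fields <- list(id = parts[1], species = NA_character_, tissues = "",
                 source = "genome", gene_id = NA_character_,
                 location = NA_character_)
  for (p in parts[-1]) {
    kv <- regmatches(p, regexec("^([A-Za-z_]+)=(.*)$", p))[[1]]
    if (length(kv) == 3) {
      key <- kv[2]; val <- kv[3]
      if (key == "tissue") fields$tissues <- val
      else if (key == "gene") fields$gene_id <- val
      else if (key == "species") fields$species <- gsub("_", " ", val)
      else if (key %in% c("source", "location")) fields[[key]] <- val
    }
  }
  fields
}

#' Read a protein FASTA file into a protein_set
#'
#' The header's first whitespace-delimited token is the record id; optional
#' `key=value` fields in the description (`species=`, `tissue=`, `source=`,
#' `gene=`, `location=`) populate the corresponding columns. Tissue values may
#' be comma-separated.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return A [protein_set].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0 ||
      !any(startsWith(readLines(path, n = 50L, warn = FALSE), ">"))) {
    warning("empty FASTA file: ", path)
    return(protein_set(character(0), character(0)))
  }
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  fields <- lapply(headers, .parse_fasta_header)
  protein_set(
    id = vapply(fields, `[[`, "", "id"),
    sequence = as.character(aas),
    species = vapply(fields, `[[`, "", "species"),
    tissues = vapply(fields, `[[`, "", "tissues"),
    source = vapply(fields, `[[`, "", "source"),
    gene_id = vapply(fields, `[[`, "", "gene_id"),
    location = vapply(fields, `[[`, "", "location"))
}

#' Write a protein_set to FASTA
#'
#' Headers are `id key=value ...` with only non-empty metadata emitted, so
#' that [read_fasta] followed by `write_fasta` is byte-identical on files the
#' package wrote itself.
#'
#' @param x a [protein_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "protein_set"))
  hdr <- x$id
  add <- function(hdr, key, val, transform = identity) {
    keep <- !is.na(val) & nzchar(val)
    hdr[keep] <- paste0(hdr[keep], " ", key, "=", transform(val[keep]))
    hdr
  }
  hdr <- add(hdr, "species", x$species, function(v) gsub(" ", "_", v))
  hdr <- add(hdr, "tissue", x$tissues)
  hdr <- add(hdr, "source", ifelse(x$source == "genome", "", x$source))
  hdr <- add(hdr, "gene", x$gene_id)
  hdr <- add(hdr, "location", x$location)
  aas <- Biostrings::AAStringSet(setNames(x$sequence, hdr))
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Construct a gene model
#'
#' Exon coordinates are 1-based inclusive (GFF3 convention), one matrix of
#' `(start, end)` rows per mRNA isoform. Exons within an isoform must be
#' non-overlapping; they are sorted by start.
#'
#' @param gene_id gene identifier.
#' @param mrnas list of two-column numeric matrices of exon coordinates.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, mrnas, strand = "+") {
  stopifnot(length(mrnas) >= 1, strand %in% c("+", "-"))
  mrnas <- lapply(mrnas, function(m) {
    m <- matrix(as.numeric(m), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    if (nrow(m) < 1) stop("mRNA with no exons in gene ", gene_id)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[, 2] < m[, 1])) stop("exon end < start in gene ", gene_id)
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
      stop("overlapping exons in gene ", gene_id)
    m
  })
  structure(list(gene_id = gene_id, mrnas = mrnas, strand = strand),
            class = "gene_model")
}

#' Count introns in a gene model
#'
#' Returns the minimum over isoforms of (number of exons - 1); one number per
#' gene, so multi-isoform genes report their least-interrupted transcript.
#' S-RNases characteristically have only one or two introns, which the
#' screening engine uses as a selection rule.
#'
#' @param model a [gene_model].
#' @return Non-negative integer intron count.
#' @examples
#' intron_count(gene_model("g", list(cbind(c(1, 201), c(100, 300)))))
#' @export
intron_count <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  min(vapply(model$mrnas, nrow, 0L)) - 1L
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`exon` features (via rtracklayer) into a named list
#' of [gene_model] objects keyed by gene id.
#'
#' @param path path to a GFF3 file.
#' @return Named list of [gene_model] objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mr <- gr[typ %in% c("mRNA", "transcript")]
  mrna2gene <- setNames(vapply(mr$Parent, `[`, "", 1), mr$ID)
  ex <- gr[typ == "exon"]
  exon_parent <- vapply(ex$Parent, `[`, "", 1)
  genes <- gr[typ == "gene"]
  gstrand <- setNames(as.character(GenomicRanges::strand(genes)), genes$ID)
  out <- list()
  for (gid in unique(unname(mrna2gene))) {
    mids <- names(mrna2gene)[mrna2gene == gid]
    mrnas <- lapply(mids, function(mid) {
      e <- ex[exon_parent == mid]
      cbind(start = GenomicRanges::start(e), end = GenomicRanges::end(e))
    })
    st <- gstrand[gid]
    if (is.na(st) || !st %in% c("+", "-")) st <- "+"
    out[[gid]] <- gene_model(gid, mrnas, strand = st)
  }
  out
}

#' Construct a gene-by-tissue expression matrix
#'
#' @param values non-negative numeric matrix, genes in rows (rownames) and
#'   tissues in columns (colnames).
#' @param unit `"counts"` (raw fragment counts) or `"FPKM"`.
#' @param lengths named numeric vector of transcript lengths in nt; required
#'   when `unit = "counts"`.
#' @param library_sizes named numeric vector of total mapped fragments per
#'   tissue; required when `unit = "counts"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, unit = c("counts", "FPKM"),
                              lengths = NULL, library_sizes = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and tissue colnames")
  if (any(values < 0)) stop("negative expression value")
  if (unit == "counts") {
    if (is.null(lengths) || is.null(library_sizes))
      stop("unit 'counts' requires transcript lengths and library sizes")
    miss <- setdiff(rownames(values), names(lengths))
    if (length(miss)) stop("missing transcript length for gene(s): ",
                           paste(miss, collapse = ", "))
    miss <- setdiff(colnames(values), names(library_sizes))
    if (length(miss)) stop("missing library size for tissue(s): ",
                           paste(miss, collapse = ", "))
    if (any(lengths[rownames(values)] <= 0)) stop("transcript lengths must be > 0")
    if (any(library_sizes[colnames(values)] <= 0)) stop("library sizes must be > 0")
  }
  structure(list(values = values, unit = unit, lengths = lengths,
                 library_sizes = library_sizes),
            class = "expression_matrix")
}

#' Read a gene-by-tissue expression table
#'
#' Expects a TSV with gene ids in the first column and one column per tissue.
#' For raw counts, companion tables of transcript lengths (`gene_id`,
#' `length`) and library sizes (`tissue`, `library_size`) must be supplied.
#'
#' @param path path to the expression TSV.
#' @param unit `"counts"` or `"FPKM"`.
#' @param lengths_path optional path to a transcript-length TSV.
#' @param library_sizes_path optional path to a library-size TSV.
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, unit = c("counts", "FPKM"),
                            lengths_path = NULL, library_sizes_path = NULL) {
  unit <- match.arg(unit)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1)
    stop("ragged expression table; line ",
         which(nf != nf[1])[1], " has ", nf[which(nf != nf[1])[1]],
         " fields (expected ", nf[1], ")")
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  lengths <- library_sizes <- NULL
  if (!is.null(lengths_path)) {
    lt <- read.delim(lengths_path, stringsAsFactors = FALSE)
    lengths <- setNames(as.numeric(lt[[2]]), lt[[1]])
  }
  if (!is.null(library_sizes_path)) {
    st <- read.delim(library_sizes_path, stringsAsFactors = FALSE)
    library_sizes <- setNames(as.numeric(st[[2]]), st[[1]])
  }
  expression_matrix(values, unit, lengths, library_sizes)
}

#' Write an expression matrix to TSV
#'
#' @param em an [expression_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  tab <- data.frame(gene_id = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a labelled reference panel
#'
#' A reference panel pairs protein sequences of known class with class labels
#' used for homology gating and clade placement. Valid labels are
#' `"S-RNase"`, `"Class-I"`, `"Class-II"`, `"SSK1"`, `"SKP1-other"` and
#' `"outgroup"`.
#'
#' @param proteins a [protein_set] of reference sequences.
#' @param labels named character vector mapping every record id to its class.
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(proteins, labels) {
  stopifnot(inherits(proteins, "protein_set"))
  miss <- setdiff(proteins$id, names(labels))
  if (length(miss)) stop("unlabelled panel record(s): ",
                         paste(miss, collapse = ", "))
  labels <- labels[proteins$id]
  ok <- c("S-RNase", "Class-I", "Class-II", "SSK1", "SKP1-other", "outgroup")
  if (!all(labels %in% ok))
    stop("unknown class label(s): ",
         paste(setdiff(labels, ok), collapse = ", "))
  if (length(unique(labels)) < 2)
    stop("reference panel must contain at least two classes")
  structure(list(proteins = proteins, labels = labels),
            class = "reference_panel")
}

#' Read a reference panel from FASTA plus a label table
#'
#' @param fasta_path FASTA file of reference proteins.
#' @param labels_path two-column TSV (`id`, `class`); a header line is
#'   detected and skipped.
#' @return A [reference_panel].
#' @export
read_panel <- function(fasta_path, labels_path) {
  prot <- read_fasta(fasta_path)
  lt <- read.delim(labels_path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(lt[1, 1]), "id")) lt <- lt[-1, , drop = FALSE]
  reference_panel(prot, setNames(as.character(lt[[2]]), lt[[1]]))
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("protein_set: %d record(s)\n", nrow(x)))
  NextMethod()
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d gene(s) x %d tissue(s)\n",
              x$unit, nrow(x$values), ncol(x$values)))
  print(utils::head(x$values))
  invisible(x)
}
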