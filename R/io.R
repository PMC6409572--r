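#' Read a FASTA file with validation
#'
#' Wraps [Biostrings::readBStringSet()] with the checks a mining run needs:
#' duplicate record ids and non-IUPAC characters are rejected with an error
#' naming the offending record, sequences are uppercased, and DNA input
#' containing `U` (RNA) is rejected with an explanatory message.
#'
#' @param path FASTA file path.
#' @param type `"dna"` or `"protein"`.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA file: ", path)
  ids <- names(raw)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (type == "dna") {
    if (any(grepl("U", seqs, fixed = TRUE))) {
      bad <- ids[grepl("U", seqs, fixed = TRUE)]
      stop("record(s) ", paste(bad, collapse = ", "),
           " contain 'U': RNA input is not accepted, supply DNA (T not U)")
    }
    ok <- grepl("^[ACGTNRYSWKMBDHV]*$", seqs)
    if (!all(ok))
      stop("non-IUPAC DNA characters in record(s): ",
           paste(ids[!ok], collapse = ", "))
    Biostrings::DNAStringSet(setNames(seqs, ids))
  } else {
    ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYBJZX*]*$", seqs)
    if (!all(ok))
      stop("non-IUPAC protein characters in record(s): ",
           paste(ids[!ok], collapse = ", "))
    Biostrings::AAStringSet(setNames(seqs, ids))
  }
}

#' Write sequences to FASTA
#'
#' @param records a named `XStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    if (is.null(names(records))) stop("records must be named")
    records <- Biostrings::BStringSet(records)
  }
  Biostrings::writeXStringSet(records, path)
  invisible(path)
}

# ---- gene model tables -----------------------------------------------------

# The canonical in-memory representation of gene models is a data.frame with
# 0-based half-open coordinates; GFF3 (1-based inclusive) conversion happens
# only at the file boundary.
model_columns <- function() {
  c("gene_id", "contig", "start", "end", "strand", "status",
    "group_label", "subfamily_id")
}

#' Export gene models as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 output is 1-based
#' inclusive. Status, group and subfamily are carried in column-9
#' attributes. Rows are ordered deterministically by (contig, start,
#' gene_id).
#'
#' @param models data.frame with at least `gene_id`, `contig`, `start`,
#'   `end`, `strand`, and optionally `status`, `group_label`,
#'   `subfamily_id`.
#' @param path output GFF3 path.
#' @param contig_lengths optional named vector used to validate that models
#'   lie inside their contig.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff <- function(models, path, contig_lengths = NULL) {
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in%
                  names(models)))
  if (any(models$start >= models$end))
    stop("model coordinates must satisfy start < end")
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[models$contig]
    if (any(is.na(len)) || any(models$start < 0) || any(models$end > len))
      stop("model coordinate outside contig bounds")
  }
  models <- models[order(models$contig, models$start, models$gene_id), ,
                   drop = FALSE]
  attr_of <- function(i) {
    parts <- c(sprintf("ID=%s", models$gene_id[i]))
    for (nm in c("status", "group_label", "subfamily_id")) {
      if (nm %in% names(models) && !is.na(models[[nm]][i]))
        parts <- c(parts, sprintf("%s=%s", nm, models[[nm]][i]))
    }
    paste(parts, collapse = ";")
  }
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(models)), function(i) {
               paste(models$contig[i], "orminer", "gene",
                     models$start[i] + 1L, models$end[i],
                     ".", models$strand[i], ".", attr_of(i), sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Re-import a gene-model GFF3 written by [write_gene_models_gff()]
#'
#' @param path GFF3 path.
#' @return data.frame of models with 0-based half-open coordinates.
#' @export
read_gene_models_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    gene_id = as.character(gr$ID),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  for (nm in c("status", "group_label", "subfamily_id")) {
    df[[nm]] <- if (nm %in% names(S4Vectors::mcols(gr)))
      as.character(S4Vectors::mcols(gr)[[nm]]) else NA_character_
  }
  df[order(df$contig, df$start, df$gene_id), , drop = FALSE]
}

#' Write and read interval tables as BED
#'
#' BED is the package's native interval format (0-based half-open, matching
#' internal coordinates). `name`, `score`, `strand` follow BED6.
#'
#' @param intervals data.frame with `contig`, `start`, `end`, `name`,
#'   optionally `score` and `strand`.
#' @param path file path.
#' @return `write_bed`: `path`, invisibly; `read_bed`: a data.frame.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("contig", "start", "end", "name") %in% names(intervals)))
  score <- if ("score" %in% names(intervals)) intervals$score else 0
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  df <- data.frame(intervals$contig, intervals$start, intervals$end,
                   intervals$name, score, strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[seq_len(min(6, ncol(df)))] <-
    c("contig", "start", "end", "name", "score", "strand")[seq_len(min(6, ncol(df)))]
  df
}

#' Write a data.frame as a TSV report
#'
#' @param df data.frame.
#' @param path output path.
#' @param comment optional comment lines written as a `#` header.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_report <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
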