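# ORF rescue and gene-model construction: extend candidate loci to
# start/stop codons within a bp flank, record premature stops and
# frameshifts, and translate strand-aware.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Strand-space view of a contig: the sequence read 5'->3' on the gene's
# strand, with coordinate converters to/from the forward strand.
strand_space <- function(contig_seq, strand) {
  L <- length(contig_seq)
  seq <- if (strand == "+") contig_seq else
    Biostrings::reverseComplement(contig_seq)
  list(seq = as.character(seq), L = L, strand = strand)
}

ss_from_forward <- function(ss, start, end) {
  if (ss$strand == "+") c(start, end) else c(ss$L - end, ss$L - start)
}

ss_to_forward <- function(ss, start, end) {
  if (ss$strand == "+") c(start, end) else c(ss$L - end, ss$L - start)
}

codon_at <- function(seqchr, pos) substr(seqchr, pos + 1, pos + 3)

#' Rescue an open reading frame around a candidate locus
#'
#' Searches up to `flank_bp` upstream of the locus, in the reading frame of
#' its 5'-most supporting hit, for a start codon: the most upstream
#' in-frame `ATG` not preceded (in frame) by a stop codon, which maximizes
#' ORF length. Downstream, the nearest in-frame stop codon within
#' `flank_bp` closes the model. Scans clamp at contig edges; a missing
#' terminus leaves `has_start`/`has_stop` `FALSE`. Premature stops and
#' frameshifts (frame changes between chained hits of the best query) are
#' recorded as disruptions.
#'
#' @param locus one row of [select_best_hits()] output (with its `hits`).
#' @param contigs named [Biostrings::DNAStringSet].
#' @param flank_bp flank searched for start/stop codons (default 1000).
#' @return a one-row data.frame gene model (0-based half-open forward
#'   coordinates) with a `disruptions` list-column.
#' @export
rescue_orf <- function(locus, contigs, flank_bp = 1000) {
  contig_seq <- contigs[[locus$contig]]
  if (is.null(contig_seq)) stop("locus contig not found: ", locus$contig)
  if (locus$end > length(contig_seq) || locus$start < 0)
    stop("locus outside contig bounds")
  ss <- strand_space(contig_seq, locus$strand)
  hits <- locus$hits[[1]]
  bh <- hits[hits$query_id == locus$best_query_id, , drop = FALSE]
  iv <- t(mapply(function(s, e) ss_from_forward(ss, s, e),
                 bh$genome_start, bh$genome_end))
  bh$ss_start <- iv[, 1]
  bh$ss_end <- iv[, 2]
  bh <- bh[order(bh$ss_start), , drop = FALSE]
  bh$phase <- bh$ss_start %% 3

  L5 <- bh$ss_start[1]
  phase5 <- bh$phase[1]
  E3 <- max(bh$ss_end)
  phase3 <- bh$phase[which.max(bh$ss_end)]

  # upstream: most upstream in-frame ATG before any in-frame stop
  start_pos <- NA_integer_
  p <- L5
  while (p >= 0 && L5 - p <= flank_bp) {
    cod <- codon_at(ss$seq, p)
    if (nchar(cod) == 3) {
      if (p < L5 && cod %in% STOP_CODONS) break
      if (cod == "ATG") start_pos <- p
    }
    p <- p - 3
  }
  has_start <- !is.na(start_pos)
  cds_start <- if (has_start) start_pos else L5

  # downstream: nearest in-frame stop
  has_stop <- FALSE
  q <- E3 + ((phase3 - E3) %% 3)
  cds_end <- E3
  while (q + 3 <= ss$L && q + 3 - E3 <= flank_bp) {
    if (codon_at(ss$seq, q) %in% STOP_CODONS) {
      has_stop <- TRUE
      cds_end <- q + 3
      break
    }
    q <- q + 3
  }
  if (!has_stop) cds_end <- max(E3, cds_start + 3)

  disruptions <- find_disruptions(ss, bh, cds_start, cds_end)
  fwd <- ss_to_forward(ss, cds_start, cds_end)
  protein <- translate_cds(substr(ss$seq, cds_start + 1, cds_end))
  n_cod <- (cds_end - cds_start) %/% 3
  length_aa <- n_cod - as.integer(has_stop)

  model <- data.frame(
    gene_id = locus$locus_id, contig = locus$contig,
    start = as.integer(fwd[1]), end = as.integer(fwd[2]),
    strand = locus$strand,
    has_start = has_start, has_stop = has_stop,
    length_aa = as.integer(length_aa),
    n_stops = sum(vapply(disruptions, function(d) d$kind == "stop",
                         logical(1))),
    n_frameshifts = sum(vapply(disruptions,
                               function(d) d$kind == "frameshift",
                               logical(1))),
    protein = protein,
    best_query_id = locus$best_query_id,
    best_evalue = locus$best_evalue,
    stringsAsFactors = FALSE)
  model$disruptions <- I(list(disruptions))
  model
}

# Disruptions of a rescued model, in strand space: frame changes between
# chained best-query hits are frameshifts at the inter-hit junction;
# in-frame stop codons inside each same-frame segment (excluding the
# terminal stop codon) are premature stops.
find_disruptions <- function(ss, bh, cds_start, cds_end) {
  segs <- list()
  seg_start <- cds_start
  seg_phase <- bh$phase[1]
  disruptions <- list()
  if (nrow(bh) > 1) {
    for (i in seq_len(nrow(bh))[-1]) {
      if (bh$phase[i] != seg_phase) {
        junction <- bh$ss_start[i]
        segs[[length(segs) + 1]] <- list(start = seg_start, end = junction,
                                         phase = seg_phase)
        disruptions[[length(disruptions) + 1]] <- list(
          kind = "frameshift",
          codon_index = as.integer((junction - cds_start) %/% 3))
        seg_start <- junction
        seg_phase <- bh$phase[i]
      }
    }
  }
  segs[[length(segs) + 1]] <- list(start = seg_start, end = cds_end,
                                   phase = seg_phase)
  for (seg in segs) {
    p <- seg$start + ((seg$phase - seg$start) %% 3)
    while (p + 3 <= seg$end) {
      if (p + 3 < cds_end && codon_at(ss$seq, p) %in% STOP_CODONS) {
        disruptions[[length(disruptions) + 1]] <- list(
          kind = "stop", codon_index = as.integer((p - cds_start) %/% 3))
      }
      p <- p + 3
    }
  }
  idx <- order(vapply(disruptions, function(d) d$codon_index, integer(1)))
  disruptions[idx]
}

translate_cds <- function(cds_chr) {
  n <- 3 * (nchar(cds_chr) %/% 3)
  if (n < 3) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds_chr, 1, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

#' Translate a gene model from its genomic coordinates
#'
#' Standard genetic code, strand-aware. Internal stop codons are rendered
#' `*` (kept, for pseudogene reporting); a trailing stop is trimmed.
#'
#' @param model one-row gene-model data.frame (`contig`, `start`, `end`,
#'   `strand`).
#' @param contigs named [Biostrings::DNAStringSet].
#' @return protein string.
#' @export
translate_model <- function(model, contigs) {
  if (model$end - model$start < 3) stop("CDS shorter than one codon")
  contig_seq <- contigs[[model$contig]]
  if (is.null(contig_seq)) stop("model contig not found: ", model$contig)
  if (model$start < 0 || model$end > length(contig_seq))
    stop("CDS outside contig bounds")
  ss <- strand_space(contig_seq, model$strand)
  iv <- ss_from_forward(ss, model$start, model$end)
  translate_cds(substr(ss$seq, iv[1] + 1, iv[2]))
}

#' Build gene models for all candidate loci
#'
#' Runs [rescue_orf()] on every locus, then deduplicates overlapping
#' same-strand models keeping the lower-e-value locus (one gene, one
#' model).
#'
#' @param loci data.frame from [select_best_hits()].
#' @param contigs named [Biostrings::DNAStringSet].
#' @param flank_bp rescue flank in bp.
#' @return data.frame of gene models.
#' @export
build_gene_models <- function(loci, contigs, flank_bp = 1000) {
  if (nrow(loci) == 0) stop("no candidate loci")
  models <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i)
    rescue_orf(loci[i, ], contigs, flank_bp = flank_bp)))
  dedupe_models(models)
}

# Overlapping rescued models on one contig collapse to the one with the
# lowest supporting e-value; this removes both same-strand duplicates and
# the weak antisense shadow of a strong sense model (one locus, one gene).
dedupe_models <- function(models) {
  keep <- rep(TRUE, nrow(models))
  ord <- order(models$best_evalue)
  taken <- list()
  for (i in ord) {
    key <- models$contig[i]
    ivs <- taken[[key]]
    overlaps <- FALSE
    if (!is.null(ivs)) {
      overlaps <- any(models$start[i] < ivs[, 2] & models$end[i] > ivs[, 1])
    }
    if (overlaps) {
      keep[i] <- FALSE
    } else {
      taken[[key]] <- rbind(ivs, c(models$start[i], models$end[i]))
    }
  }
  out <- models[keep, , drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
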