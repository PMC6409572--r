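# Translated homology search: six-frame translation, Smith-Waterman local
# protein alignment, Karlin-Altschul e-values, best-hit locus selection.
# Stands in for TBLASTN at desk scale; hits export in outfmt-6 layout.

# Gapped BLOSUM62 Karlin-Altschul constants, fixed for reproducibility.
KA_K <- 0.041
KA_LAMBDA <- 0.267

#' Six-frame translation with coordinate maps
#'
#' Translates a contig in all six reading frames. Each track records its
#' strand and phase so that any amino-acid interval can be mapped back to
#' the codon interval on the forward strand (see [track_to_genomic()]).
#' Codons containing `N` translate to `X`; stop codons are `*`.
#'
#' @param contig a [Biostrings::DNAString], single-element `DNAStringSet`,
#'   or DNA character string.
#' @return list of six tracks, named `+1`, `+2`, `+3`, `-1`, `-2`, `-3`;
#'   each a list with `peptide`, `strand`, `phase`, `contig_len`.
#' @export
six_frame_translate <- function(contig) {
  dna <- as_dnastring(contig)
  L <- length(dna)
  rc <- Biostrings::reverseComplement(dna)
  tracks <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") dna else rc
    for (phase in 0:2) {
      ncod <- (L - phase) %/% 3
      pep <- if (ncod > 0) {
        sub <- Biostrings::subseq(src, start = phase + 1,
                                  end = phase + 3 * ncod)
        as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
      } else ""
      nm <- paste0(strand, phase + 1)
      tracks[[nm]] <- list(peptide = pep, strand = strand, phase = phase,
                           contig_len = L, frame = nm)
    }
  }
  tracks
}

as_dnastring <- function(x) {
  if (is(x, "DNAString")) return(x)
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1)
    return(x[[1]])
  }
  Biostrings::DNAString(x)
}

#' Map an amino-acid interval of a translation track to forward-strand bp
#'
#' @param track one track from [six_frame_translate()].
#' @param aa_start,aa_end 0-based half-open residue interval on the track.
#' @return integer `c(start, end)`, 0-based half-open on the forward strand.
#' @export
track_to_genomic <- function(track, aa_start, aa_end) {
  s <- track$phase + 3 * aa_start
  e <- track$phase + 3 * aa_end
  if (track$strand == "+") c(s, e) else c(track$contig_len - e,
                                          track$contig_len - s)
}

#' Optimal local protein alignment (Smith-Waterman, affine gaps)
#'
#' BLOSUM62 scoring with BLAST-style gap costs (a gap of length L costs
#' `gap_open + L * gap_extend`). Traceback ties prefer diagonal, then up,
#' then left, so results are deterministic.
#'
#' @param query,target protein strings (BLOSUM62 alphabet).
#' @param gap_open,gap_extend gap penalties.
#' @return list with `score`, `query_range` and `target_range` (1-based
#'   inclusive), `identities`, `columns` (alignment columns incl. gaps),
#'   `gapopen`.
#' @export
local_align_protein <- function(query, target, gap_open = 11,
                                gap_extend = 1) {
  if (!nzchar(query) || !nzchar(target))
    stop("local alignment requires non-empty sequences")
  res <- cpp_sw_align(encode_protein(query), encode_protein(target),
                      blosum62(), gap_open, gap_extend)
  list(score = res$score,
       query_range = c(res$qstart + 1L, res$qend),
       target_range = c(res$tstart + 1L, res$tend),
       identities = res$identities, pairs = res$pairs,
       columns = res$columns, gapopen = res$gapopen)
}

# Minimum raw score whose e-value is <= evalue_max for query length m and
# database size n. Infinite when evalue_max <= 0.
min_raw_score <- function(m, n, evalue_max) {
  if (evalue_max <= 0) return(Inf)
  ceiling(log(KA_K * m * n / evalue_max) / KA_LAMBDA)
}

evalue_of <- function(score, m, n) KA_K * m * n * exp(-KA_LAMBDA * score)

bitscore_of <- function(score) (KA_LAMBDA * score - log(KA_K)) / log(2)

empty_hits <- function() {
  data.frame(query_id = character(), contig = character(),
             frame = character(), strand = character(),
             genome_start = integer(), genome_end = integer(),
             qstart = integer(), qend = integer(),
             aln_len_aa = integer(), identities = integer(),
             mismatch = integer(), gapopen = integer(),
             raw_score = integer(), bitscore = numeric(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

#' Search a genome with a protein query panel
#'
#' Six-frame translated Smith-Waterman search. Every returned hit has
#' e-value `<= evalue_max`; e-values follow the Karlin-Altschul formula
#' `K * m * n * exp(-lambda * score)` with `m` the query length and `n` the
#' total translated length of all frames. Short positive hits are kept --
#' there is no alignment-length floor.
#'
#' By default candidate windows come from an exact 4-mer two-hit seed scan
#' (`prefilter = TRUE`); with `prefilter = FALSE` every frame is scanned
#' exhaustively in overlapping tiles. Both modes extract multiple
#' non-overlapping HSPs per window by recursive splitting.
#'
#' @param queries named protein sequences ([Biostrings::AAStringSet] or
#'   named character vector).
#' @param contigs named [Biostrings::DNAStringSet].
#' @param evalue_max e-value cutoff (default 10).
#' @param prefilter use the seed prefilter (default) or exhaustive tiling.
#' @param gap_open,gap_extend gap penalties.
#' @return data.frame of hits (one row per HSP) with genomic 0-based
#'   half-open coordinates on the forward strand.
#' @export
search_genome <- function(queries, contigs, evalue_max = 10,
                          prefilter = TRUE, gap_open = 11, gap_extend = 1) {
  if (length(queries) == 0) stop("empty query panel")
  queries <- as_named_character(queries)
  stopifnot(!is.null(names(contigs)))
  if (evalue_max <= 0) return(empty_hits())

  all_tracks <- lapply(seq_along(contigs),
                       function(i) six_frame_translate(contigs[[i]]))
  names(all_tracks) <- names(contigs)
  n_total <- sum(vapply(all_tracks, function(tr)
    sum(vapply(tr, function(t) nchar(t$peptide), integer(1))), numeric(1)))

  enc_tracks <- lapply(all_tracks, function(tr)
    lapply(tr, function(t) encode_protein(t$peptide)))

  out <- list()
  for (q in names(queries)) {
    qenc <- encode_protein(queries[[q]])
    m <- length(qenc)
    smin <- min_raw_score(m, n_total, evalue_max)
    if (!is.finite(smin)) next
    for (cg in names(all_tracks)) {
      for (fr in names(all_tracks[[cg]])) {
        track <- all_tracks[[cg]][[fr]]
        tenc <- enc_tracks[[cg]][[fr]]
        if (length(tenc) < 4) next
        windows <- if (prefilter) {
          cpp_seed_windows(qenc, tenc, 4L, nrow(blosum62()), 8L, 48L,
                           100L)
        } else {
          tile_windows(length(tenc), tile = 4000L, overlap = 2L * m)
        }
        if (nrow(windows) == 0) next
        hsps <- cpp_sw_hsps(qenc, tenc, blosum62(), gap_open, gap_extend,
                            as.integer(smin), windows, 16L)
        if (nrow(hsps) == 0) next
        hsps <- unique(as.data.frame(hsps))
        coords <- t(apply(hsps, 1, function(r)
          track_to_genomic(track, r[["tstart"]], r[["tend"]])))
        out[[length(out) + 1]] <- data.frame(
          query_id = q, contig = cg, frame = fr, strand = track$strand,
          genome_start = as.integer(coords[, 1]),
          genome_end = as.integer(coords[, 2]),
          qstart = hsps$qstart + 1L, qend = hsps$qend,
          aln_len_aa = hsps$columns, identities = hsps$identities,
          mismatch = hsps$pairs - hsps$identities, gapopen = hsps$gapopen,
          raw_score = hsps$score,
          bitscore = bitscore_of(hsps$score),
          evalue = evalue_of(hsps$score, m, n_total),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  hits[order(hits$contig, hits$genome_start, hits$query_id), ,
       drop = FALSE]
}

tile_windows <- function(n, tile, overlap) {
  if (n <= tile) return(matrix(c(0L, n), nrow = 1))
  starts <- seq(0L, n - 1L, by = tile - overlap)
  m <- cbind(starts, pmin(starts + tile, n))
  m <- m[m[, 1] < m[, 2], , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

as_named_character <- function(x) {
  if (is(x, "XStringSet")) x <- as.character(x)
  stopifnot(is.character(x), !is.null(names(x)))
  as.list(x)
}

#' Chain hits into candidate loci and keep the best query per locus
#'
#' Hits on one contig and strand are chained into a locus when the genomic
#' gap between them is at most `chain_gap_bp` (frameshift-split HSPs of one
#' gene chain together; tandem neighbours stay apart). Per locus the best
#' hit -- lowest e-value, then longest alignment, then highest bitscore,
#' then lexicographically smallest query id -- defines `best_query_id`.
#'
#' @param hits data.frame from [search_genome()].
#' @param chain_gap_bp maximum chained gap in bp (default 5000).
#' @return data.frame of loci (sorted by contig, start) with a list-column
#'   `hits` carrying each locus's supporting hits.
#' @export
select_best_hits <- function(hits, chain_gap_bp = 5000) {
  if (nrow(hits) == 0) {
    return(data.frame(locus_id = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), best_query_id = character(),
                      n_hits = integer(), stringsAsFactors = FALSE))
  }
  loci <- list()
  for (key in unique(paste(hits$contig, hits$strand))) {
    sub <- hits[paste(hits$contig, hits$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$genome_start, sub$genome_end), , drop = FALSE]
    cur <- 1L
    grp <- integer(nrow(sub))
    grp[1] <- cur
    run_end <- sub$genome_end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$genome_start[i] - run_end > chain_gap_bp) cur <- cur + 1L
      grp[i] <- cur
      run_end <- max(run_end, sub$genome_end[i])
    }
    for (g in unique(grp)) {
      lh <- sub[grp == g, , drop = FALSE]
      best <- lh[order(lh$evalue, -lh$aln_len_aa, -lh$bitscore,
                       lh$query_id), , drop = FALSE][1, ]
      loci[[length(loci) + 1]] <- list(
        contig = lh$contig[1], strand = lh$strand[1],
        start = min(lh$genome_start), end = max(lh$genome_end),
        best_query_id = best$query_id, best_evalue = best$evalue,
        n_hits = nrow(lh), hits = lh)
    }
  }
  df <- data.frame(
    contig = vapply(loci, `[[`, character(1), "contig"),
    strand = vapply(loci, `[[`, character(1), "strand"),
    start = vapply(loci, function(x) as.integer(x$start), integer(1)),
    end = vapply(loci, function(x) as.integer(x$end), integer(1)),
    best_query_id = vapply(loci, `[[`, character(1), "best_query_id"),
    best_evalue = vapply(loci, `[[`, numeric(1), "best_evalue"),
    n_hits = vapply(loci, function(x) as.integer(x$n_hits), integer(1)),
    stringsAsFactors = FALSE)
  ord <- order(df$contig, df$start)
  df <- df[ord, , drop = FALSE]
  df$locus_id <- sprintf("locus_%03d", seq_len(nrow(df)))
  df$hits <- I(lapply(loci, `[[`, "hits")[ord])
  rownames(df) <- NULL
  df[, c("locus_id", "contig", "strand", "start", "end", "best_query_id",
         "best_evalue", "n_hits", "hits")]
}

#' Format hits as a BLAST outfmt-6 style table
#'
#' Twelve columns with outfmt-6 semantics (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore);
#' subject coordinates are 1-based and reversed on the minus strand.
#'
#' @param hits data.frame from [search_genome()].
#' @return data.frame with the 12 outfmt-6 columns.
#' @export
hits_outfmt6 <- function(hits) {
  plus <- hits$strand == "+"
  sstart <- ifelse(plus, hits$genome_start + 1L, hits$genome_end)
  send <- ifelse(plus, hits$genome_end, hits$genome_start + 1L)
  data.frame(qseqid = hits$query_id, sseqid = hits$contig,
             pident = round(100 * hits$identities /
                              pmax(hits$aln_len_aa, 1L), 2),
             length = hits$aln_len_aa, mismatch = hits$mismatch,
             gapopen = hits$gapopen, qstart = hits$qstart,
             qend = hits$qend, sstart = sstart, send = send,
             evalue = hits$evalue, bitscore = round(hits$bitscore, 1),
             stringsAsFactors = FALSE)
}
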