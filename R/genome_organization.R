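# Genomic organization: megabase-rule cluster detection and per-chromosome
# summary tables of functional genes and pseudogenes.

#' Detect genomic OR clusters by the megabase rule
#'
#' A linear sweep per contig over models sorted by start: a new cluster
#' opens when the end-to-start gap to the previous gene exceeds `gap_bp`
#' (genes more than 1 Mb apart fall in different clusters). Singleton
#' clusters are allowed.
#'
#' @param models data.frame with `gene_id`, `contig`, `start`, `end`.
#' @param gap_bp cluster-splitting gap in bp (default 1 Mb).
#' @return data.frame of clusters with a `members` list-column of gene ids
#'   ordered by start.
#' @export
detect_clusters <- function(models, gap_bp = 1e6) {
  if (nrow(models) == 0) {
    return(data.frame(cluster_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), stringsAsFactors = FALSE))
  }
  models <- models[order(models$contig, models$start), , drop = FALSE]
  out <- list()
  for (cg in unique(models$contig)) {
    sub <- models[models$contig == cg, , drop = FALSE]
    grp <- cumsum(c(1, as.integer(
      sub$start[-1] - sub$end[-nrow(sub)] > gap_bp)))
    for (g in unique(grp)) {
      mem <- sub[grp == g, , drop = FALSE]
      out[[length(out) + 1]] <- list(contig = cg, start = min(mem$start),
                                     end = max(mem$end),
                                     members = mem$gene_id)
    }
  }
  df <- data.frame(
    cluster_id = sprintf("cluster_%02d", seq_along(out)),
    contig = vapply(out, `[[`, character(1), "contig"),
    start = vapply(out, function(x) as.integer(x$start), integer(1)),
    end = vapply(out, function(x) as.integer(x$end), integer(1)),
    n_members = vapply(out, function(x) length(x$members), integer(1)),
    stringsAsFactors = FALSE)
  df$members <- I(lapply(out, `[[`, "members"))
  df
}

round_half_up <- function(x) floor(x + 0.5)

#' Per-chromosome summary of the OR repertoire
#'
#' One row per chromosome with functional and pseudogene counts, the
#' pseudogene percentage (integer, half-up), the total, and the cluster
#' count; one pooled row for unplaced scaffolds (no percentage or cluster
#' count); one Total row. Truncated models are excluded from the table (it
#' summarizes functional genes and pseudogenes) but are retained in GFF
#' output elsewhere.
#'
#' @param models classified models (`status` set).
#' @param clusters data.frame from [detect_clusters()].
#' @param unplaced_pattern regex identifying unplaced scaffold names.
#' @param unplaced_label row label for the pooled unplaced row.
#' @return data.frame with columns `contig`, `n_functional`, `n_pseudo`,
#'   `pseudo_pct`, `total`, `n_clusters`.
#' @export
summarize_by_chromosome <- function(models, clusters,
                                    unplaced_pattern = "^(LGUN|scaffold|SCAF)",
                                    unplaced_label = "LGUN") {
  models <- models[!is.na(models$status) &
                     models$status %in% c("functional", "pseudogene"), ,
                   drop = FALSE]
  row_of <- function(label, sub, n_clusters, with_pct = TRUE) {
    nf <- sum(sub$status == "functional")
    np <- sum(sub$status == "pseudogene")
    tot <- nf + np
    data.frame(contig = label, n_functional = nf, n_pseudo = np,
               pseudo_pct = if (with_pct && tot > 0)
                 as.integer(round_half_up(100 * np / tot)) else NA_integer_,
               total = tot, n_clusters = n_clusters,
               stringsAsFactors = FALSE)
  }
  contigs <- sort(unique(models$contig))
  placed <- contigs[!grepl(unplaced_pattern, contigs)]
  rows <- lapply(placed, function(cg)
    row_of(cg, models[models$contig == cg, , drop = FALSE],
           sum(clusters$contig == cg)))
  unplaced <- models[grepl(unplaced_pattern, models$contig), , drop = FALSE]
  if (nrow(unplaced) > 0)
    rows <- c(rows, list(row_of(unplaced_label, unplaced, NA_integer_,
                                with_pct = FALSE)))
  total_row <- row_of("Total", models,
                      sum(!grepl(unplaced_pattern, clusters$contig)))
  do.call(rbind, c(rows, list(total_row)))
}

#' Reconstruct a model table from published per-chromosome counts
#'
#' Builds a minimal gene-model table (and matching cluster layout) whose
#' per-chromosome functional/pseudogene counts and cluster counts equal a
#' published summary, so that table arithmetic (percentages, totals) can
#' be recomputed through [summarize_by_chromosome()] and
#' [detect_clusters()] rather than copied. Genes are laid out in as many
#' >1 Mb-separated blocks per contig as the published cluster count.
#'
#' @param counts data.frame with `contig`, `n_functional`, `n_pseudo`,
#'   `n_clusters` (`NA` cluster count for unplaced scaffolds).
#' @param gene_len,spacing_bp,cluster_sep_bp layout constants; the
#'   defaults keep within-cluster gaps far below and between-cluster gaps
#'   far above the megabase rule.
#' @return data.frame of models usable with [detect_clusters()] and
#'   [summarize_by_chromosome()].
#' @export
repertoire_from_counts <- function(counts, gene_len = 1000,
                                   spacing_bp = 10000,
                                   cluster_sep_bp = 1500000) {
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    n_total <- counts$n_functional[i] + counts$n_pseudo[i]
    if (n_total == 0) next
    statuses <- c(rep("functional", counts$n_functional[i]),
                  rep("pseudogene", counts$n_pseudo[i]))
    ncl <- counts$n_clusters[i]
    if (is.na(ncl)) ncl <- 1L
    block <- sort(rep(seq_len(ncl), length.out = n_total))
    within <- stats::ave(seq_along(block), block, FUN = seq_along)
    start <- (block - 1) * cluster_sep_bp +
      (within - 1) * (gene_len + spacing_bp)
    rows[[i]] <- data.frame(
      gene_id = sprintf("%s_g%03d", counts$contig[i], seq_len(n_total)),
      contig = counts$contig[i], start = as.integer(start),
      end = as.integer(start + gene_len), strand = "+",
      status = statuses, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Strand agreement within clusters
#'
#' Fraction of each cluster's members lying on the cluster's majority
#' strand, plus the overall fraction across all clustered genes. Tandemly
#' duplicated OR clusters typically share one transcriptional orientation,
#' so values near 1 are expected.
#'
#' @param clusters data.frame from [detect_clusters()].
#' @param models models with `gene_id` and `strand`.
#' @return list with `per_cluster` (data.frame) and `overall` (numeric).
#' @export
orientation_stats <- function(clusters, models) {
  strand_of <- setNames(models$strand, models$gene_id)
  frac <- vapply(clusters$members, function(mem) {
    s <- strand_of[mem]
    max(table(s)) / length(s)
  }, numeric(1))
  n <- clusters$n_members
  list(per_cluster = data.frame(cluster_id = clusters$cluster_id,
                                agreement = frac,
                                stringsAsFactors = FALSE),
       overall = sum(frac * n) / sum(n))
}
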