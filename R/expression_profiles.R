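# Expression summaries from read-count matrices: FPKM computation and
# per-stage comparisons. Read mapping and transcript assembly are out of
# scope; counts are the input.

#' FPKM from a fragment-count matrix
#'
#' `fpkm = count * 1e9 / (gene_length_bp * library_total_fragments)`,
#' with per-library totals taken as the column sums of the input matrix
#' (self-contained; no external mapped-read figure).
#'
#' @param count_matrix numeric matrix, genes x libraries, counts >= 0.
#' @param gene_lengths named vector of gene lengths in bp (> 0).
#' @return FPKM matrix of the same shape.
#' @export
compute_fpkm <- function(count_matrix, gene_lengths) {
  stopifnot(is.matrix(count_matrix), !is.null(rownames(count_matrix)))
  if (any(count_matrix < 0)) stop("counts must be >= 0")
  len <- gene_lengths[rownames(count_matrix)]
  if (anyNA(len)) stop("missing gene length(s): ",
                       paste(rownames(count_matrix)[is.na(len)],
                             collapse = ", "))
  if (any(len <= 0)) stop("zero or negative gene length(s): ",
                          paste(names(len)[len <= 0], collapse = ", "))
  totals <- colSums(count_matrix)
  if (any(totals <= 0)) stop("library with zero total fragments")
  sweep(count_matrix / len, 2, totals, "/") * 1e9
}

#' Per-stage expression summary
#'
#' Per-stage means over replicates, expressed-gene and
#' differential-expression calls, and a long-format table ready for
#' heatmap plotting. A gene is "expressed" when its mean FPKM reaches
#' `expressed_min_fpkm` in at least one stage, and "differential" when it
#' is expressed and the fold change between the highest- and lowest-mean
#' stages reaches `fold_change_cutoff` (a declared fold-change stand-in,
#' not a statistical test).
#'
#' @param fpkm FPKM matrix, genes x libraries.
#' @param design data.frame with `library` and `stage` columns mapping
#'   every column of `fpkm` to a stage.
#' @param fold_change_cutoff fold change calling differential expression.
#' @param expressed_min_fpkm mean-FPKM floor for the expressed call.
#' @return list: `stage_means` (genes x stages), `genes` (per-gene table
#'   with fold_change, expressed, differential, direction),
#'   `n_expressed`, `n_differential`, `heatmap` (long-format data.frame).
#' @export
stage_summary <- function(fpkm, design, fold_change_cutoff = 2,
                          expressed_min_fpkm = 1) {
  stopifnot(all(c("library", "stage") %in% names(design)))
  missing_lib <- setdiff(colnames(fpkm), design$library)
  if (length(missing_lib) > 0)
    stop("library missing from design: ",
         paste(missing_lib, collapse = ", "))
  stages <- sort(unique(design$stage))
  stage_means <- vapply(stages, function(st) {
    libs <- design$library[design$stage == st]
    rowMeans(fpkm[, libs, drop = FALSE])
  }, numeric(nrow(fpkm)))
  if (is.null(dim(stage_means)))
    stage_means <- matrix(stage_means, ncol = length(stages),
                          dimnames = list(rownames(fpkm), stages))
  hi <- apply(stage_means, 1, max)
  lo <- apply(stage_means, 1, min)
  fc <- ifelse(lo > 0, hi / lo, ifelse(hi > 0, Inf, 1))
  expressed <- hi >= expressed_min_fpkm
  differential <- expressed & fc >= fold_change_cutoff
  direction <- colnames(stage_means)[apply(stage_means, 1, which.max)]
  genes <- data.frame(gene_id = rownames(fpkm), fold_change = fc,
                      expressed = expressed, differential = differential,
                      direction = direction, stringsAsFactors = FALSE,
                      row.names = NULL)
  heatmap <- data.frame(
    gene_id = rep(rownames(stage_means), times = ncol(stage_means)),
    stage = rep(colnames(stage_means), each = nrow(stage_means)),
    mean_fpkm = as.vector(stage_means), stringsAsFactors = FALSE)
  list(stage_means = stage_means, genes = genes,
       n_expressed = sum(expressed), n_differential = sum(differential),
       heatmap = heatmap)
}

#' Simulate a fragment-count matrix with planted differential genes
#'
#' Poisson counts around stage-specific means: the first half of the
#' `n_diff` planted genes carries a `fold` times higher mean in the
#' first stage (emulating stronger olfactory-epithelium expression early
#' in development), the second half in the last stage -- balancing
#' library totals so FPKM normalization does not smear the planted
#' effect onto flat genes; the remainder are flat across stages.
#'
#' @param n_genes number of genes.
#' @param stages character vector of stage names.
#' @param n_reps replicates per stage.
#' @param n_diff number of planted differential genes.
#' @param fold planted fold change.
#' @param base_mean baseline mean fragment count.
#' @param gene_length_bp common gene length used for the FPKM
#'   denominator.
#' @param seed integer seed.
#' @return list: `counts` matrix, `design` data.frame, `gene_lengths`,
#'   `truth` (logical vector of planted differential genes).
#' @export
simulate_expression_counts <- function(n_genes = 100,
                                       stages = c("30dph", "adult"),
                                       n_reps = 3, n_diff = 30, fold = 4,
                                       base_mean = 200,
                                       gene_length_bp = 1000, seed = 1L) {
  set.seed(seed)
  libs <- paste0(rep(stages, each = n_reps), "_r", seq_len(n_reps))
  design <- data.frame(library = libs,
                       stage = rep(stages, each = n_reps),
                       stringsAsFactors = FALSE)
  truth <- c(rep(TRUE, n_diff), rep(FALSE, n_genes - n_diff))
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  mu <- matrix(base_mean, nrow = n_genes, ncol = length(libs),
               dimnames = list(genes, libs))
  n_up <- ceiling(n_diff / 2)
  if (n_up > 0)
    mu[seq_len(n_up), design$stage == stages[1]] <- base_mean * fold
  if (n_diff > n_up)
    mu[seq(n_up + 1, n_diff),
       design$stage == stages[length(stages)]] <- base_mean * fold
  counts <- matrix(stats::rpois(length(mu), lambda = mu), nrow = n_genes,
                   dimnames = dimnames(mu))
  list(counts = counts, design = design,
       gene_lengths = setNames(rep(gene_length_bp, n_genes), genes),
       truth = setNames(truth, genes))
}
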