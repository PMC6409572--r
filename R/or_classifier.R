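# Reciprocal OR / non-OR filtering, Kyte-Doolittle transmembrane segment
# prediction, and the three-way functional / pseudogene / truncated call.

#' Bundle OR references and non-OR GPCR decoys into a reference panel
#'
#' @param or_proteins named protein vector (or `AAStringSet`) of OR
#'   references.
#' @param or_groups character vector of group labels (one per OR
#'   reference), drawn from the Greek group nomenclature (alpha..lambda).
#' @param decoy_proteins named protein vector of non-OR GPCR decoys.
#' @return a `reference_panel` list.
#' @export
reference_panel <- function(or_proteins, or_groups, decoy_proteins) {
  if (length(or_proteins) == 0 || length(decoy_proteins) == 0)
    stop("panel must be non-empty on both sides")
  or_proteins <- unlist(as_named_character(or_proteins))
  decoy_proteins <- unlist(as_named_character(decoy_proteins))
  if (length(or_groups) != length(or_proteins))
    stop("every OR reference needs a group label")
  if (length(intersect(names(or_proteins), names(decoy_proteins))) > 0)
    stop("OR and decoy id sets must be disjoint")
  structure(list(or = or_proteins, or_groups = setNames(
    as.character(or_groups), names(or_proteins)),
    decoy = decoy_proteins), class = "reference_panel")
}

#' Reciprocal best-match assignment: OR or non-OR
#'
#' Aligns the candidate locally against every OR reference and every non-OR
#' GPCR decoy; the side holding the single best bitscore labels the
#' candidate. Ties go to non-OR (conservative: a candidate that matches a
#' decoy as well as an OR is discarded).
#'
#' @param candidate_protein protein string.
#' @param panel a [reference_panel()].
#' @return list with `label` (`"OR"`/`"non-OR"`), `best_match`,
#'   `best_score`, `margin` (best OR score minus best decoy score).
#' @export
reciprocal_assign <- function(candidate_protein, panel) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!nzchar(candidate_protein)) stop("empty candidate protein")
  score_vs <- function(refs) vapply(refs, function(r)
    local_align_protein(candidate_protein, r)$score, numeric(1))
  s_or <- score_vs(panel$or)
  s_dec <- score_vs(panel$decoy)
  best_or <- max(s_or); best_dec <- max(s_dec)
  if (best_or > best_dec) {
    list(label = "OR", best_match = names(panel$or)[which.max(s_or)],
         best_score = best_or, margin = best_or - best_dec)
  } else {
    list(label = "non-OR",
         best_match = names(panel$decoy)[which.max(s_dec)],
         best_score = best_dec, margin = best_or - best_dec)
  }
}

# Kyte-Doolittle hydropathy values.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Predict transmembrane segments by Kyte-Doolittle hydropathy
#'
#' A sliding window (default 19 residues) of mean hydropathy is computed at
#' every window center; a segment is a maximal run of centers whose mean
#' exceeds `cutoff` (default 1.6); segments closer than `merge_aa` residues
#' are merged. Residues without a hydropathy value (`*`, `X`) count as
#' strongly hydrophilic.
#'
#' @param protein protein string.
#' @param window window size (odd, default 19).
#' @param cutoff mean-hydropathy threshold (default 1.6).
#' @param merge_aa merge distance between segments (default 5).
#' @return list with `count` and `segments` (matrix of 1-based start/end
#'   residue positions of window centers).
#' @export
predict_tm_segments <- function(protein, window = 19, cutoff = 1.6,
                                merge_aa = 5) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < window) return(list(count = 0L, segments = NULL))
  h <- KD_SCALE[chars]
  h[is.na(h)] <- -4.5
  means <- as.numeric(stats::filter(h, rep(1 / window, window),
                                    sides = 2))
  centers <- which(!is.na(means) & means > cutoff)
  if (length(centers) == 0) return(list(count = 0L, segments = NULL))
  breaks <- which(diff(centers) > merge_aa)
  starts <- centers[c(1, breaks + 1)]
  ends <- centers[c(breaks, length(centers))]
  list(count = length(starts), segments = cbind(start = starts, end = ends))
}

#' Three-way status call for one gene model
#'
#' Implements the classification rules of the identification protocol:
#' truncated if the model lacks a start and/or stop codon; otherwise
#' pseudogene if the model is at least `min_protein_len_aa` long and
#' carries stop/frameshift disruptions; otherwise functional if it is at
#' least that long, disruption-free, and codes for at least
#' `min_tm_segments` transmembrane segments. Models failing all three are
#' dropped (`NA` status) with the reason recorded. Truncation takes
#' precedence over pseudogene: a truncated model with an internal stop is
#' truncated.
#'
#' @param has_start,has_stop start/stop codon flags from rescue.
#' @param length_aa model length in amino acids.
#' @param n_disruptions number of stop/frameshift disruptions.
#' @param tm_count predicted transmembrane segment count.
#' @param config a [pipeline_config()].
#' @return list with `status` (`"functional"`, `"pseudogene"`,
#'   `"truncated"`, or `NA`) and `reason` for dropped models.
#' @export
classify_status <- function(has_start, has_stop, length_aa, n_disruptions,
                            tm_count, config = pipeline_config()) {
  if (!(has_start && has_stop))
    return(list(status = "truncated", reason = NA_character_))
  if (length_aa >= config$min_protein_len_aa && n_disruptions > 0)
    return(list(status = "pseudogene", reason = NA_character_))
  if (length_aa >= config$min_protein_len_aa && n_disruptions == 0 &&
      tm_count >= config$min_tm_segments)
    return(list(status = "functional", reason = NA_character_))
  reason <- if (length_aa < config$min_protein_len_aa)
    sprintf("intact model below %d aa", config$min_protein_len_aa)
  else sprintf("fewer than %d TM segments", config$min_tm_segments)
  list(status = NA_character_, reason = reason)
}

#' Classify gene models against a reference panel
#'
#' Applies [reciprocal_assign()] to discard candidates matching non-OR
#' GPCRs best, then calls [classify_status()] on each remaining model.
#' Dropped models (non-OR, or failing every status definition) are removed;
#' attrition is logged per stage.
#'
#' @param models data.frame from [build_gene_models()].
#' @param panel a [reference_panel()].
#' @param config a [pipeline_config()].
#' @return data.frame of classified OR models with `status`, `tm_count`,
#'   `best_panel_match`, `panel_margin` columns.
#' @export
classify_models <- function(models, panel, config = pipeline_config()) {
  if (!is.null(models$status) && any(!is.na(models$status)))
    stop("status already set")
  rec <- lapply(models$protein, reciprocal_assign, panel = panel)
  is_or <- vapply(rec, function(r) r$label == "OR", logical(1))
  or_log("classify", sum(!is_or), " candidate(s) discarded as non-OR GPCR")
  models <- models[is_or, , drop = FALSE]
  rec <- rec[is_or]
  tm <- vapply(models$protein, function(p)
    predict_tm_segments(p, config$tm_window, config$tm_cutoff,
                        config$tm_merge_aa)$count, integer(1))
  calls <- lapply(seq_len(nrow(models)), function(i)
    classify_status(models$has_start[i], models$has_stop[i],
                    models$length_aa[i],
                    models$n_stops[i] + models$n_frameshifts[i],
                    tm[i], config))
  status <- vapply(calls, function(x) x$status, character(1))
  dropped <- is.na(status)
  for (i in which(dropped))
    or_log("classify", models$gene_id[i], " dropped: ", calls[[i]]$reason)
  models$status <- status
  models$tm_count <- as.integer(tm)
  models$best_panel_match <- vapply(rec, `[[`, character(1), "best_match")
  models$panel_margin <- vapply(rec, `[[`, numeric(1), "margin")
  out <- models[!dropped, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classification report table
#'
#' @param models classified models from [classify_models()].
#' @return data.frame: gene_id, status, length_aa, n_stops, n_frameshifts,
#'   tm_count, best_panel_match, bitscore margin.
#' @export
classification_report <- function(models) {
  data.frame(gene_id = models$gene_id, status = models$status,
             length_aa = models$length_aa, n_stops = models$n_stops,
             n_frameshifts = models$n_frameshifts,
             tm_count = models$tm_count,
             best_panel_match = models$best_panel_match,
             margin = models$panel_margin, stringsAsFactors = FALSE)
}
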