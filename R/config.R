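#' Pipeline configuration
#'
#' Collects the thresholds that drive the identification protocol: the
#' e-value cutoff of the translated search, the flank searched for rescued
#' start/stop codons, the minimum protein length and transmembrane-segment
#' count of a functional OR, the megabase gap that separates genomic
#' clusters, the identity cutoffs for subfamily/family clustering, and the
#' fold-change cutoff of the expression summary.
#'
#' @param evalue_max maximum e-value retained by the translated search.
#' @param flank_bp flank (bp) searched up/downstream for start/stop codons.
#' @param min_protein_len_aa minimum model length (aa) for the
#'   functional/pseudogene calls.
#' @param min_tm_segments minimum number of predicted transmembrane
#'   segments for a functional call.
#' @param cluster_gap_bp genomic gap (bp) beyond which adjacent OR genes
#'   fall in different clusters.
#' @param subfamily_identity_pct protein percent-identity cutoff joining two
#'   genes into one subfamily.
#' @param family_identity_pct percent-identity cutoff for families.
#' @param fold_change_cutoff fold change calling a gene differentially
#'   expressed between stages.
#' @param chain_gap_bp genomic gap (bp) within which translated-search hits
#'   on one strand are chained into a single candidate locus.
#' @param tm_window,tm_cutoff,tm_merge_aa Kyte-Doolittle window size, mean
#'   hydropathy cutoff, and merge distance for transmembrane prediction.
#' @param bootstrap_reps bootstrap replicates for group assignment support.
#' @param seed integer seed for stochastic steps.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(evalue_max = 10,
                            flank_bp = 1000,
                            min_protein_len_aa = 250,
                            min_tm_segments = 7,
                            cluster_gap_bp = 1e6,
                            subfamily_identity_pct = 60,
                            family_identity_pct = 40,
                            fold_change_cutoff = 2,
                            chain_gap_bp = 5000,
                            tm_window = 19,
                            tm_cutoff = 1.6,
                            tm_merge_aa = 5,
                            bootstrap_reps = 100,
                            seed = 1L) {
  cfg <- list(evalue_max = evalue_max, flank_bp = flank_bp,
              min_protein_len_aa = min_protein_len_aa,
              min_tm_segments = min_tm_segments,
              cluster_gap_bp = cluster_gap_bp,
              subfamily_identity_pct = subfamily_identity_pct,
              family_identity_pct = family_identity_pct,
              fold_change_cutoff = fold_change_cutoff,
              chain_gap_bp = chain_gap_bp,
              tm_window = tm_window, tm_cutoff = tm_cutoff,
              tm_merge_aa = tm_merge_aa,
              bootstrap_reps = bootstrap_reps,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  thr <- c("evalue_max", "min_protein_len_aa", "min_tm_segments",
           "cluster_gap_bp", "fold_change_cutoff", "chain_gap_bp",
           "tm_window")
  for (nm in thr) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be > 0")
  }
  if (cfg$flank_bp < 0) stop("config field 'flank_bp' must be >= 0")
  for (nm in c("subfamily_identity_pct", "family_identity_pct")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v > 100)
      stop("config field '", nm, "' must lie in (0, 100]")
  }
  invisible(cfg)
}

#' Read or write a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers where possible. Used so a run can be reproduced from a single
#' artifact; command-line flags override file values.
#'
#' @param path file path.
#' @param overrides named list applied on top of the file contents.
#' @return `read_config`: a [pipeline_config()]; `write_config`: `path`,
#'   invisibly.
#' @export
read_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed config line: ", ln)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (!is.na(num)) num else val
  }
  kv[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, kv)
}

#' @rdname read_config
#' @param cfg a [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lines <- vapply(names(unclass(cfg)), function(nm) {
    sprintf("%s = %s", nm, format(cfg[[nm]], scientific = FALSE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
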