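# Conserved-motif scanning (exact/degenerate patterns or PWMs) and
# N-glycosylation sequon detection, with motif-pattern frequency tables.

#' Define a motif
#'
#' A motif is either a (degenerate) regular-expression pattern or a
#' position weight matrix with a log-odds score threshold. Motif lengths
#' are restricted to 5-50 residues.
#'
#' @param motif_id short id (conventionally Roman numerals I-V).
#' @param pattern regular expression over amino acids (exact consensus
#'   strings are the simplest case).
#' @param pwm numeric matrix (rows = amino acids, columns = positions) of
#'   log-odds scores.
#' @param threshold minimum best-window log-odds score for a PWM match.
#' @return a `motif_definition` list.
#' @export
motif_definition <- function(motif_id, pattern = NULL, pwm = NULL,
                             threshold = NULL) {
  if (is.null(pattern) == is.null(pwm))
    stop("supply exactly one of pattern or pwm")
  len <- if (!is.null(pattern)) {
    nchar(gsub("\\[[^]]*\\]", "x", pattern))
  } else ncol(pwm)
  if (len < 5 || len > 50) stop("motif length must lie in [5, 50]")
  if (!is.null(pwm) && is.null(threshold))
    stop("a PWM motif needs a score threshold")
  structure(list(motif_id = motif_id, pattern = pattern, pwm = pwm,
                 threshold = threshold, length = len),
            class = "motif_definition")
}

#' The package's default conserved-motif set
#'
#' Five exact consensus motifs; the synthetic-genome generator embeds the
#' same set in every OR-like protein it plants, so presence/absence
#' scanning is verifiable end to end. These are configuration defaults,
#' not motifs discovered from real OR sequences.
#'
#' @return list of five [motif_definition()]s named I-V.
#' @export
default_motif_set <- function() {
  cons <- c(I = "LHQPRYFDE", II = "KAYDRYEQT", III = "SERNKDTHS",
            IV = "PNLNPERYG", V = "KSTCGSHEL")
  lapply(setNames(names(cons), names(cons)), function(id)
    motif_definition(id, pattern = cons[[id]]))
}

#' Read a motif set from a TSV config file
#'
#' Two columns: `motif_id`, `pattern`.
#'
#' @param path TSV path.
#' @return list of [motif_definition()]s.
#' @export
read_motif_set <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("motif_id", "pattern") %in% names(df)))
  lapply(setNames(seq_len(nrow(df)), df$motif_id), function(i)
    motif_definition(df$motif_id[i], pattern = df$pattern[i]))
}

#' Scan a protein for a motif set
#'
#' A regex motif is present where its pattern matches; a PWM motif is
#' present where the best sliding-window log-odds score reaches its
#' threshold.
#'
#' @param protein protein string.
#' @param motif_set list of [motif_definition()]s (default
#'   [default_motif_set()]).
#' @return list with `present` (named logical) and `positions` (named list
#'   of 1-based match start positions).
#' @export
scan_motifs <- function(protein, motif_set = default_motif_set()) {
  if (length(motif_set) == 0) stop("empty motif set")
  present <- logical(length(motif_set))
  positions <- vector("list", length(motif_set))
  names(present) <- names(positions) <-
    vapply(motif_set, `[[`, character(1), "motif_id")
  for (k in seq_along(motif_set)) {
    m <- motif_set[[k]]
    if (!is.null(m$pattern)) {
      hit <- gregexpr(m$pattern, protein)[[1]]
      if (hit[1] != -1) {
        present[k] <- TRUE
        positions[[k]] <- as.integer(hit)
      }
    } else {
      sc <- pwm_window_scores(protein, m$pwm)
      best <- which(sc >= m$threshold)
      if (length(best) > 0) {
        present[k] <- TRUE
        positions[[k]] <- best
      }
    }
  }
  list(present = present, positions = positions)
}

pwm_window_scores <- function(protein, pwm) {
  chars <- strsplit(protein, "")[[1]]
  L <- ncol(pwm)
  n <- length(chars) - L + 1
  if (n < 1) return(numeric(0))
  vapply(seq_len(n), function(i) {
    idx <- cbind(match(chars[i:(i + L - 1)], rownames(pwm)), seq_len(L))
    if (anyNA(idx[, 1])) return(-Inf)
    sum(pwm[idx])
  }, numeric(1))
}

#' Motif-pattern frequency table
#'
#' Tabulates the observed presence patterns over a set of genes, with
#' counts and two-decimal percentages; the all-motifs row comes first,
#' remaining patterns follow by decreasing count. Absent motifs are named
#' in the pattern as `(III)`-style parenthesized ids.
#'
#' @param presence logical matrix (rows = genes, columns = motif ids) or
#'   data.frame with a `gene_id` column and logical motif columns.
#' @return data.frame: pattern, n, pct.
#' @export
motif_pattern_frequencies <- function(presence) {
  if (is.data.frame(presence)) {
    rn <- presence$gene_id
    presence <- as.matrix(presence[, setdiff(names(presence), "gene_id"),
                                   drop = FALSE])
    rownames(presence) <- rn
  }
  ids <- colnames(presence)
  pattern_of <- function(row) {
    if (all(row)) return("all")
    paste0("missing ", paste0("(", ids[!row], ")", collapse = ""))
  }
  pats <- apply(presence, 1, pattern_of)
  tab <- sort(table(pats), decreasing = TRUE)
  df <- data.frame(pattern = names(tab), n = as.integer(tab),
                   pct = round(100 * as.integer(tab) / nrow(presence), 2),
                   stringsAsFactors = FALSE)
  df <- df[order(df$pattern != "all", -df$n, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Candidate N-linked glycosylation sequons
#'
#' All 1-based positions `i` with `protein[i] == N`, `protein[i+1] != P`
#' and `protein[i+2]` in `{S, T}` (the N-X-S/T rule with proline
#' exclusion). A deterministic stand-in for neural-network glycosylation
#' predictors.
#'
#' @param protein protein string.
#' @return integer vector of sequon start positions (possibly empty).
#' @export
find_sequons <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  if (n < 3) return(integer(0))
  i <- seq_len(n - 2)
  which(chars[i] == "N" & chars[i + 1] != "P" &
          chars[i + 2] %in% c("S", "T"))
}
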