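# Independent NG86 oracles: exhaustive path enumeration for pairwise
# difference counts, and direct enumeration of synonymous site fractions.

oracle_ng86_diffs <- function(ca, cb) {
  gc <- Biostrings::GENETIC_CODE
  aa <- function(c) unname(gc[c])
  diffs <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(diffs) == 0) return(c(0, 0))
  walk <- function(cur, remaining, allow_stops) {
    if (length(remaining) == 0) return(list(c(0, 0)))
    out <- list()
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(cb, pos, pos)
      if (!allow_stops && aa(nxt) == "*") next
      step <- if (aa(nxt) != "*" && aa(nxt) == aa(cur)) c(1, 0)
        else c(0, 1)
      for (tail in walk(nxt, setdiff(remaining, pos), allow_stops))
        out[[length(out) + 1]] <- step + tail
    }
    out
  }
  paths <- walk(ca, diffs, allow_stops = FALSE)
  if (length(paths) == 0) paths <- walk(ca, diffs, allow_stops = TRUE)
  Reduce(`+`, paths) / length(paths)
}

oracle_syn_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  nt <- c("T", "C", "A", "G")
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(nt, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (gc[mut] != "*" && gc[mut] == gc[codon]) syn <- syn + 1
    }
  }
  3 * syn / 9
}
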