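# Shared fixtures. The tiny simulated genome and its pipeline run are
# computed once per test session and reused; the default-scale run used
# by the acceptance checks is likewise memoised.

.fixtures <- new.env(parent = emptyenv())

tiny_sim <- function(seed = 1) {
  key <- paste0("sim_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- assemble_genome(tiny_generator_spec(seed = seed))
  .fixtures[[key]]
}

tiny_run <- function(seed = 1) {
  key <- paste0("run_", seed)
  if (is.null(.fixtures[[key]])) {
    sim <- tiny_sim(seed)
    .fixtures[[key]] <- run_or_pipeline(
      sim$contigs, sim$panels$queries, sim$panels$references,
      config = pipeline_config(bootstrap_reps = 0))
  }
  .fixtures[[key]]
}

default_sim <- function(seed = 1) {
  key <- paste0("dsim_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- assemble_genome(generator_spec(seed = seed))
  .fixtures[[key]]
}

default_run <- function(seed = 1) {
  key <- paste0("drun_", seed)
  if (is.null(.fixtures[[key]])) {
    sim <- default_sim(seed)
    .fixtures[[key]] <- run_or_pipeline(
      sim$contigs, sim$panels$queries, sim$panels$references,
      config = pipeline_config(bootstrap_reps = 0))
  }
  .fixtures[[key]]
}

random_protein <- function(n, aas = c("A", "R", "N", "D", "C", "Q", "E",
                                      "G", "H", "I", "L", "K", "M", "F",
                                      "P", "S", "T", "W", "Y", "V")) {
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent hand-rolled codon-table translation used as an oracle
# against the package's Biostrings-backed translation.
oracle_translate <- function(dna) {
  tab <- c(TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L",
           CTC = "L", CTA = "L", CTG = "L", ATT = "I", ATC = "I",
           ATA = "I", ATG = "M", GTT = "V", GTC = "V", GTA = "V",
           GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S",
           CCT = "P", CCC = "P", CCA = "P", CCG = "P", ACT = "T",
           ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
           GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
           TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
           AAT = "N", AAC = "N", AAA = "K", AAG = "K", GAT = "D",
           GAC = "D", GAA = "E", GAG = "E", TGT = "C", TGC = "C",
           TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R",
           CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
           GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  n <- nchar(dna) %/% 3
  cods <- substring(dna, 3 * seq_len(n) - 2, 3 * seq_len(n))
  out <- tab[cods]
  out[is.na(out)] <- "X"
  paste(out, collapse = "")
}

oracle_revcomp <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(dna, "")[[1]]]), collapse = "")
}
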