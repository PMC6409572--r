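# Six-frame translation, Smith-Waterman engine, e-value bookkeeping and
# best-hit locus selection.

test_that("six-frame translation matches a hand-rolled codon oracle", {
  expect_identical(six_frame_translate("ATGAAATAG")[["+1"]]$peptide,
                   "MK*")
  set.seed(11)
  for (rep in 1:5) {
    dna <- random_dna(300)
    tracks <- six_frame_translate(dna)
    rc <- oracle_revcomp(dna)
    for (phase in 0:2) {
      n <- (300 - phase) %/% 3
      expect_identical(tracks[[paste0("+", phase + 1)]]$peptide,
                       oracle_translate(substr(dna, phase + 1,
                                               phase + 3 * n)))
      expect_identical(tracks[[paste0("-", phase + 1)]]$peptide,
                       oracle_translate(substr(rc, phase + 1,
                                               phase + 3 * n)))
    }
  }
  # reverse frame equals forward frame of the reverse complement
  tr <- six_frame_translate("ATGAAATAG")
  tr_rc <- six_frame_translate(oracle_revcomp("ATGAAATAG"))
  expect_identical(tr[["-1"]]$peptide, tr_rc[["+1"]]$peptide)
})

test_that("track coordinates map residues back to forward-strand codons", {
  dna <- random_dna(90)
  tracks <- six_frame_translate(dna)
  tr <- tracks[["+2"]]
  expect_identical(track_to_genomic(tr, 3, 5), c(1 + 9, 1 + 15))
  tr <- tracks[["-1"]]
  iv <- track_to_genomic(tr, 0, 1)
  expect_identical(iv, c(87, 90))
})

test_that("local alignment equals an independent optimal-score oracle", {
  b62 <- orminer:::blosum62()
  # worked classic example
  expect_identical(local_align_protein("HEAGAWGHEE", "PAWHEAE")$score,
                   17L)
  # identical sequences score the diagonal sum with full identity
  p <- random_protein(50)
  self <- local_align_protein(p, p)
  expect_identical(self$score,
                   sum(diag(b62[strsplit(p, "")[[1]],
                                strsplit(p, "")[[1]]])))
  expect_identical(self$identities, 50L)
  set.seed(21)
  for (i in 1:40) {
    a <- random_protein(sample(15:70, 1))
    b <- random_protein(sample(15:70, 1))
    ours <- local_align_protein(a, b)$score
    oracle <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = b62, gapOpening = 11, gapExtension = 1,
      type = "local"))
    expect_identical(ours, as.integer(oracle))
    # optimality: never above the self score of the shorter sequence
    expect_lte(ours, local_align_protein(a, a)$score)
  }
  expect_error(local_align_protein("AC-D", "ACD"), "alphabet")
  expect_error(local_align_protein("", "ACD"), "non-empty")
})

test_that("e-values follow the Karlin-Altschul size dependence", {
  sim <- tiny_sim()
  q <- sim$panels$queries[1]
  hits1 <- search_genome(q, sim$contigs[1])
  expect_gt(nrow(hits1), 0)
  expect_true(all(hits1$evalue <= 10))
  # doubling the searched database doubles every hit e-value
  doubled <- c(sim$contigs[1], setNames(sim$contigs[1], "copy"))
  hits2 <- search_genome(q, doubled)
  h2 <- hits2[hits2$contig == names(sim$contigs)[1], ]
  m <- merge(hits1, h2,
             by = c("query_id", "frame", "genome_start", "genome_end"))
  expect_gt(nrow(m), 0)
  expect_equal(m$evalue.y, 2 * m$evalue.x, tolerance = 1e-12)
  # a zero cutoff yields no hits at all
  expect_identical(nrow(search_genome(q, sim$contigs[1],
                                      evalue_max = 0)), 0L)
  expect_error(search_genome(character(0), sim$contigs), "empty query")
})

test_that("every planted gene is recovered by at least one locus", {
  sim <- tiny_sim()
  hits <- search_genome(sim$panels$queries, sim$contigs)
  loci <- select_best_hits(hits)
  or_truth <- sim$truth[sim$truth$status != "decoy", ]
  for (i in seq_len(nrow(or_truth))) {
    tr <- or_truth[i, ]
    cand <- loci[loci$contig == tr$contig & loci$strand == tr$strand, ]
    ov <- pmax(0, pmin(cand$end, tr$end) - pmax(cand$start, tr$start))
    expect_gte(max(ov) / (tr$end - tr$start), 0.8)
  }
})

test_that("search is strand-symmetric", {
  sim <- tiny_sim()
  ctg <- sim$contigs[1]
  L <- Biostrings::width(ctg)[1]
  flipped <- Biostrings::reverseComplement(ctg)
  names(flipped) <- names(ctg)
  q <- sim$panels$queries[1]
  h1 <- search_genome(q, ctg)
  h2 <- search_genome(q, flipped)
  m1 <- h1[order(h1$genome_start), ]
  m2 <- h2[order(-h2$genome_end), ]
  expect_identical(nrow(m1), nrow(m2))
  expect_identical(m1$genome_start, L - m2$genome_end)
  expect_identical(m1$genome_end, L - m2$genome_start)
  expect_identical(m1$raw_score, m2$raw_score)
})

test_that("the seed prefilter does not change planted-gene recall", {
  # exhaustive tiling additionally reports weak random-background loci
  # (legitimate hits at e <= 10 without an exact two-hit seed); on the
  # planted genes both modes must agree exactly
  sim <- tiny_sim()
  h1 <- search_genome(sim$panels$queries, sim$contigs, prefilter = TRUE)
  h2 <- search_genome(sim$panels$queries, sim$contigs, prefilter = FALSE)
  l1 <- select_best_hits(h1)
  l2 <- select_best_hits(h2)
  or_truth <- sim$truth[sim$truth$status != "decoy", ]
  gene_loci <- function(loci) {
    idx <- vapply(seq_len(nrow(or_truth)), function(i) {
      tr <- or_truth[i, ]
      cand <- which(loci$contig == tr$contig & loci$strand == tr$strand)
      ov <- pmin(loci$end[cand], tr$end) - pmax(loci$start[cand],
                                                tr$start)
      cand[which.max(ov)]
    }, integer(1))
    out <- loci[idx, c("contig", "strand", "start", "end",
                       "best_query_id")]
    rownames(out) <- or_truth$gene_id
    out
  }
  expect_identical(gene_loci(l1), gene_loci(l2))
})

test_that("best-hit selection follows lowest e-value then longest alignment", {
  hit <- function(q, s, e, evalue, len, bits) {
    data.frame(query_id = q, contig = "c", frame = "+1", strand = "+",
               genome_start = s, genome_end = e, qstart = 1L,
               qend = len, aln_len_aa = len, identities = len,
               mismatch = 0L, gapopen = 0L, raw_score = 100L,
               bitscore = bits, evalue = evalue,
               stringsAsFactors = FALSE)
  }
  # overlapping hits from two queries: lower e-value wins
  hits <- rbind(hit("qB", 100, 400, 1e-50, 100, 200),
                hit("qA", 120, 420, 1e-10, 100, 120))
  expect_identical(select_best_hits(hits)$best_query_id, "qB")
  # equal e-values: longer alignment wins
  hits <- rbind(hit("qA", 100, 640, 1e-20, 180, 150),
                hit("qB", 100, 460, 1e-20, 120, 150))
  expect_identical(select_best_hits(hits)$best_query_id, "qA")
  # equal everything: lexicographically smallest query id
  hits <- rbind(hit("qB", 100, 400, 1e-20, 100, 150),
                hit("qA", 100, 400, 1e-20, 100, 150))
  expect_identical(select_best_hits(hits)$best_query_id, "qA")
  # hits 2 Mb apart stay separate loci
  hits <- rbind(hit("qA", 100, 400, 1e-20, 100, 150),
                hit("qA", 2e6, 2e6 + 300, 1e-20, 100, 150))
  expect_identical(nrow(select_best_hits(hits)), 2L)
})

test_that("hit tables export in outfmt-6 layout", {
  sim <- tiny_sim()
  hits <- search_genome(sim$panels$queries[1], sim$contigs[1])
  tab <- hits_outfmt6(hits)
  expect_named(tab, c("qseqid", "sseqid", "pident", "length", "mismatch",
                      "gapopen", "qstart", "qend", "sstart", "send",
                      "evalue", "bitscore"))
  minus <- tab[hits$strand == "-", ]
  if (nrow(minus) > 0) expect_true(all(minus$sstart > minus$send))
})
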