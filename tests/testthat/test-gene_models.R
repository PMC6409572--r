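# ORF rescue, disruption detection and strand-aware translation.

tiny_models <- function() {
  run <- tiny_run()
  run$models
}

test_that("translation is strand-aware and matches a codon-table oracle", {
  contigs <- Biostrings::DNAStringSet(c(c1 = "ATGGCCTAA"))
  model <- data.frame(gene_id = "g", contig = "c1", start = 0L, end = 9L,
                      strand = "+", stringsAsFactors = FALSE)
  expect_identical(translate_model(model, contigs), "MA")
  contigs_rc <- Biostrings::DNAStringSet(
    c(c1 = oracle_revcomp("ATGGCCTAA")))
  model$strand <- "-"
  expect_identical(translate_model(model, contigs_rc), "MA")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    cds <- random_dna(3 * n)
    contigs <- Biostrings::DNAStringSet(c(c1 = cds))
    model <- data.frame(gene_id = "g", contig = "c1", start = 0L,
                        end = 3L * n, strand = "+",
                        stringsAsFactors = FALSE)
    expect_identical(translate_model(model, contigs),
                     sub("\\*$", "", oracle_translate(cds)))
  }
  model <- data.frame(gene_id = "g", contig = "c1", start = 0L,
                      end = 999L, strand = "+", stringsAsFactors = FALSE)
  expect_error(translate_model(model, Biostrings::DNAStringSet(
    c(c1 = "ATGGCCTAA"))), "bounds")
})

test_that("rescued intervals equal the planted intervals exactly", {
  sim <- tiny_sim()
  models <- tiny_models()
  full <- sim$truth[sim$truth$status %in% c("functional", "pseudogene"), ]
  ev <- evaluate_recovery(models, sim$truth)
  per <- ev$per_gene[ev$per_gene$truth_status != "truncated", ]
  expect_true(all(per$exact_interval))
  # no model protein shorter than its supporting alignment span
  expect_true(all(nchar(models$protein) > 0))
  expect_identical(nrow(full) + 2L, nrow(ev$per_gene))
})

test_that("edge-truncated genes lose the expected terminus", {
  sim <- tiny_sim()
  models <- tiny_models()
  ev <- evaluate_recovery(models, sim$truth)
  tru <- sim$truth[sim$truth$status == "truncated", ]
  for (i in seq_len(nrow(tru))) {
    mid <- ev$per_gene$model_id[ev$per_gene$gene_id == tru$gene_id[i]]
    m <- models[models$gene_id == mid, ]
    if (tru$missing[i] == "start") {
      expect_false(m$has_start)
      expect_true(m$has_stop)
    } else {
      expect_true(m$has_start)
      expect_false(m$has_stop)
    }
  }
})

test_that("disruption detection recovers planted stops and frameshifts", {
  sim <- tiny_sim()
  models <- tiny_models()
  ev <- evaluate_recovery(models, sim$truth)
  map <- setNames(ev$per_gene$model_id, ev$per_gene$gene_id)
  # planted functional genes: zero false-positive disruptions
  fun <- sim$truth[sim$truth$status == "functional", ]
  for (g in fun$gene_id) {
    m <- models[models$gene_id == map[[g]], ]
    expect_identical(m$n_stops + m$n_frameshifts, 0L, info = g)
  }
  # pseudogenes: recover the planted disruption kinds and positions
  ps <- sim$truth[sim$truth$status == "pseudogene", ]
  for (i in seq_len(nrow(ps))) {
    m <- models[models$gene_id == map[[ps$gene_id[i]]], ]
    planted <- orminer:::parse_disruptions(ps$disruptions[i])
    found <- m$disruptions[[1]]
    found_kinds <- vapply(found, `[[`, character(1), "kind")
    for (d in planted) {
      if (d$kind == "stop") {
        idx <- vapply(found[found_kinds == "stop"], `[[`, integer(1),
                      "codon_index")
        expect_true(d$codon_index %in% idx, info = ps$gene_id[i])
      } else {
        expect_true("frameshift" %in% found_kinds, info = ps$gene_id[i])
      }
    }
  }
})

test_that("rescue honours the flank bound", {
  # a CDS embedded mid-contig with its ATG 150 bp upstream of the hit
  set.seed(5)
  prot <- make_or_like_protein("delta", 44)
  cds <- orminer:::reverse_translate(prot)
  left <- random_dna(3000)
  # stop guard right before the ATG so upstream scanning stops there
  left <- paste0(substr(left, 1, 2997 - 3), "TAA",
                 substr(left, 2998, 3000))
  contig <- Biostrings::DNAStringSet(
    c(c1 = paste0(substr(left, 1, 2997), "TAA", cds, random_dna(3000))))
  q <- substr(prot, 60, 250)
  hits <- search_genome(setNames(q, "q"), contig, evalue_max = 10)
  loci <- select_best_hits(hits)
  # the sense locus over the planted CDS (weak background/antisense loci
  # may also pass the permissive cutoff)
  ov <- pmax(0, pmin(loci$end, 3000 + nchar(cds)) - pmax(loci$start, 3000))
  loci <- loci[loci$strand == "+" & ov > 0.8 * nchar(cds), ]
  expect_identical(nrow(loci), 1L)
  m_full <- rescue_orf(loci[1, ], contig, flank_bp = 1000)
  expect_true(m_full$has_start)
  expect_identical(m_full$start, 3000L)
  expect_identical(m_full$end, 3000L + nchar(cds))
  expect_true(is.integer(m_full$start) && is.integer(m_full$end))
  # flank 0 confines the model to the hit interval
  m0 <- rescue_orf(loci[1, ], contig, flank_bp = 0)
  expect_false(m0$has_start)
  expect_false(m0$has_stop)
  expect_gte(m0$start, loci$start[1])
  expect_lte(m0$end, loci$end[1])
})

test_that("overlapping models deduplicate to the lower e-value locus", {
  models <- rbind(
    data.frame(gene_id = "a", contig = "c", start = 100L, end = 1000L,
               strand = "+", best_evalue = 1e-50, stringsAsFactors = FALSE),
    data.frame(gene_id = "b", contig = "c", start = 500L, end = 1500L,
               strand = "-", best_evalue = 1e-10, stringsAsFactors = FALSE),
    data.frame(gene_id = "c", contig = "c", start = 5000L, end = 6000L,
               strand = "+", best_evalue = 1e-5, stringsAsFactors = FALSE))
  out <- orminer:::dedupe_models(models)
  expect_setequal(out$gene_id, c("a", "c"))
})
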