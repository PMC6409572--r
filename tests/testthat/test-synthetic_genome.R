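# Generator contracts: protein scaffolds, pseudogenization, truncation,
# genome assembly and ground-truth bookkeeping.

test_that("generated OR-like proteins satisfy the scaffold contract", {
  for (g in c("beta", "delta", "eta")) {
    p <- make_or_like_protein(g, seed = 3)
    expect_gte(nchar(p), 300)
    expect_gte(predict_tm_segments(p)$count, 7)
    expect_true(all(scan_motifs(p)$present))
    expect_gte(length(find_sequons(p)), 1)
    expect_identical(substr(p, 1, 1), "M")
  }
})

test_that("protein generation is seed-deterministic and validates labels", {
  expect_identical(make_or_like_protein("delta", 1),
                   make_or_like_protein("delta", 1))
  expect_false(identical(make_or_like_protein("delta", 1),
                         make_or_like_protein("delta", 2)))
  expect_false(identical(make_or_like_protein("delta", 1),
                         make_or_like_protein("eta", 1)))
  expect_error(make_or_like_protein("omega", 1), "unknown group")
})

test_that("pseudogenize plants stops and frameshifts and refuses short CDS", {
  set.seed(9)
  prot <- make_or_like_protein("delta", 11)
  cds <- orminer:::reverse_translate(prot)

  ps <- pseudogenize(cds, "stop", seed = 2)
  expect_identical(nchar(ps$cds), nchar(cds))
  translated <- orminer:::translate_cds(ps$cds)
  expect_true(grepl("*", translated, fixed = TRUE))
  expect_identical(substr(ps$cds, 1, 3), "ATG")
  expect_length(ps$disruptions, 1)
  expect_identical(ps$disruptions[[1]]$kind, "stop")

  fs <- pseudogenize(cds, "frameshift", seed = 2)
  expect_identical(nchar(fs$cds) %% 3L, 2L)  # 1-nt deletion
  # translation downstream of the deletion diverges from the original
  orig <- orminer:::translate_cds(cds)
  shifted <- orminer:::translate_cds(fs$cds)
  at <- fs$disruptions[[1]]$codon_index
  expect_identical(substr(orig, 1, at - 1), substr(shifted, 1, at - 1))
  expect_false(substr(orig, at + 2, at + 20) ==
                 substr(shifted, at + 2, at + 20))

  both <- pseudogenize(cds, "both", seed = 2)
  expect_setequal(vapply(both$disruptions, `[[`, character(1), "kind"),
                  c("stop", "frameshift"))

  short <- paste0("ATG", strrep("GCT", 100), "TAA")
  expect_error(pseudogenize(short, "stop"), "250")
})

test_that("assembled genome matches its truth table exactly", {
  sim <- tiny_sim()
  spec <- sim$spec
  expect_identical(nrow(sim$truth),
                   spec$n_functional + spec$n_pseudo + spec$n_truncated +
                     spec$n_decoys)
  # strand-aware truth slicing recovers every planted sequence
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    seq <- substr(as.character(sim$contigs[[tr$contig]]),
                  tr$start + 1, tr$end)
    if (tr$strand == "-") seq <- oracle_revcomp(seq)
    expect_identical(seq, sim$gene_seqs[[tr$gene_id]],
                     info = tr$gene_id)
  }
})

test_that("genome assembly is seed-reproducible and seed-sensitive", {
  sim1 <- assemble_genome(tiny_generator_spec(seed = 7))
  sim2 <- assemble_genome(tiny_generator_spec(seed = 7))
  expect_identical(as.character(sim1$contigs), as.character(sim2$contigs))
  expect_identical(sim1$truth, sim2$truth)
  sim3 <- assemble_genome(tiny_generator_spec(seed = 8))
  expect_false(identical(as.character(sim1$contigs),
                         as.character(sim3$contigs)))
})

test_that("planted clusters respect the megabase geometry", {
  sim <- default_sim()
  or_truth <- sim$truth[sim$truth$status != "decoy", ]
  cl <- detect_clusters(or_truth, gap_bp = 1e6)
  expect_identical(nrow(cl), sim$n_clusters_planned)
  # within a cluster neighbours sit closer than the megabase rule
  for (i in seq_len(nrow(cl))) {
    mem <- or_truth[or_truth$gene_id %in% cl$members[[i]], ]
    mem <- mem[order(mem$start), ]
    if (nrow(mem) > 1)
      expect_true(all(mem$start[-1] - mem$end[-nrow(mem)] < 1e6))
  }
})

test_that("generator spec invariants are enforced", {
  expect_error(generator_spec(intercluster_gap_bp = 9e5), "1,000,000")
  expect_error(generator_spec(n_functional = -1), ">= 0")
  plan <- default_subfamily_plan()
  plan$identity_target[1] <- 55
  expect_error(generator_spec(subfamily_plan = plan), "60")
  plan <- default_subfamily_plan()
  plan$n_members[1] <- 99L
  expect_error(generator_spec(subfamily_plan = plan), "sum")
})

test_that("decoys score closer to the decoy panel than to OR queries", {
  sim <- tiny_sim()
  panel <- sim$panels$references
  dec <- sim$truth[sim$truth$status == "decoy", ]
  for (i in seq_len(nrow(dec))) {
    prot <- orminer:::translate_cds(sim$gene_seqs[[dec$gene_id[i]]])
    best_or <- max(vapply(panel$or, function(r)
      local_align_protein(prot, r)$score, numeric(1)))
    best_dec <- max(vapply(panel$decoy, function(r)
      local_align_protein(prot, r)$score, numeric(1)))
    expect_gt(best_dec, best_or)
  }
})
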