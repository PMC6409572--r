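# Percent-identity subfamily clustering and cross-species sharing.

`%+%` <- function(a, b) paste0(a, b)

test_that("pairwise identity handles substitutions and terminal gaps", {
  expect_equal(pairwise_identity("MKVLFAY", "MKVLFAY"), 100)
  expect_equal(pairwise_identity(strrep("A", 9) %+% "W",
                                 strrep("A", 9) %+% "Y"), 90)
  # terminal overhangs are excluded from the denominator
  expect_equal(pairwise_identity("KKKWWCCHH", "AAAKKKWWCCHHAAA"), 100)
  expect_error(pairwise_identity("", "MKV"), "empty")
  set.seed(71)
  for (i in 1:30) {
    a <- random_protein(sample(30:80, 1))
    b <- random_protein(sample(30:80, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("single-linkage clustering equals a brute-force union-find", {
  set.seed(81)
  base <- random_protein(120)
  mutate_at <- function(p, k) {
    ch <- strsplit(p, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- sample(c("A", "R", "N", "D", "E", "K"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:12),
    species = "s1",
    protein = c(vapply(1:4, function(i) mutate_at(base, 10),
                       character(1)),
                vapply(1:4, function(i) mutate_at(random_protein(120), 8),
                       character(1)),
                vapply(1:4, function(i) random_protein(120),
                       character(1))),
    stringsAsFactors = FALSE)
  res <- cluster_subfamilies(genes, subfamily_cutoff = 60,
                             family_cutoff = 40)
  # brute-force: union-find over all pairs with identity >= 60
  idm <- outer(genes$gene_id, genes$gene_id,
               Vectorize(function(a, b) pairwise_identity(
                 genes$protein[genes$gene_id == a],
                 genes$protein[genes$gene_id == b])))
  dimnames(idm) <- list(genes$gene_id, genes$gene_id)
  parent <- setNames(genes$gene_id, genes$gene_id)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in 1:11) for (j in (i + 1):12) {
    if (idm[i, j] >= 60)
      parent[[find(genes$gene_id[i])]] <- find(genes$gene_id[j])
  }
  roots <- vapply(genes$gene_id, find, character(1))
  oracle_part <- split(genes$gene_id, roots)
  ours_part <- split(res$gene_id, res$subfamily_id)
  canon <- function(p) unname(lapply(p[order(vapply(p, min, ""))], sort))
  expect_identical(canon(ours_part), canon(oracle_part))
})

test_that("clustering is order-invariant with canonical ids", {
  set.seed(91)
  sim <- tiny_sim()
  run <- tiny_run()
  fun <- run$models[run$models$status == "functional", ]
  genes <- data.frame(gene_id = fun$gene_id, species = "s",
                      protein = fun$protein, stringsAsFactors = FALSE)
  a <- cluster_subfamilies(genes)
  b <- cluster_subfamilies(genes[sample(nrow(genes)), ])
  expect_identical(a, b)
})

test_that("identity exactly at the cutoff joins the subfamily", {
  # two 10-mers at exactly 60% identity
  a <- "MKVLFAYWHD"
  b <- "MKVLFAEEEE"
  expect_equal(pairwise_identity(a, b), 60)
  genes <- data.frame(gene_id = c("g1", "g2"), species = "s",
                      protein = c(a, b), stringsAsFactors = FALSE)
  res <- cluster_subfamilies(genes, subfamily_cutoff = 60,
                             family_cutoff = 40)
  expect_identical(res$subfamily_id[1], res$subfamily_id[2])
  expect_error(cluster_subfamilies(genes, subfamily_cutoff = 0), "0, 100")
})

test_that("raising the cutoff refines the partition (monotonicity)", {
  run <- tiny_run()
  fun <- run$models[run$models$status == "functional", ]
  genes <- data.frame(gene_id = fun$gene_id, species = "s",
                      protein = fun$protein, stringsAsFactors = FALSE)
  loose <- cluster_subfamilies(genes, subfamily_cutoff = 50)
  tight <- cluster_subfamilies(genes, subfamily_cutoff = 70)
  # every tight subfamily lies inside one loose subfamily
  for (sf in unique(tight$subfamily_id)) {
    members <- tight$gene_id[tight$subfamily_id == sf]
    expect_identical(length(unique(
      loose$subfamily_id[loose$gene_id %in% members])), 1L)
  }
  # the subfamily partition always refines the family partition
  for (sf in unique(loose$subfamily_id)) {
    members <- loose$gene_id[loose$subfamily_id == sf]
    expect_identical(length(unique(
      loose$family_id[loose$gene_id %in% members])), 1L)
  }
})

test_that("the planted subfamily plan is recovered exactly", {
  sim <- tiny_sim()
  run <- tiny_run()
  ev <- evaluate_recovery(run$models, sim$truth)
  map <- setNames(ev$per_gene$gene_id, ev$per_gene$model_id)
  sf <- run$subfamilies
  truth_sf <- sim$truth$subfamily_id[match(map[sf$gene_id],
                                           sim$truth$gene_id)]
  tab <- table(truth_sf, sf$subfamily_id)
  # a one-to-one correspondence: each planted subfamily maps to exactly
  # one recovered subfamily and vice versa
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("sharing reports partition subfamilies by species combination", {
  # 80 subfamilies: 17 shared by exactly four species, 63 specific
  rows <- list()
  sp <- c("sich", "dila", "cyse", "taru", "gaac")
  for (i in 1:17) {
    for (s in sp[1:4]) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = sprintf("c%02d_%s", i, s), species = s,
        family_id = "F", subfamily_id = sprintf("SF%02d", i),
        stringsAsFactors = FALSE)
    }
  }
  for (i in 18:80) {
    s <- sp[1 + i %% 5]
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = sprintf("s%02d", i), species = s, family_id = "F",
      subfamily_id = sprintf("SF%02d", i), stringsAsFactors = FALSE)
  }
  rep <- sharing_report(do.call(rbind, rows))
  expect_identical(rep$total_subfamilies, 80L)
  expect_identical(sharing_fraction(rep, 4), 21L)
  expect_identical(sum(rep$combinations$n_subfamilies), 80L)
  expect_identical(sum(rep$species_specific$n_subfamilies), 63L)
  # per-species gene counts sum to each species' clustered gene total
  all_df <- do.call(rbind, rows)
  for (s in sp) {
    expect_identical(sum(rep$combinations[[paste0("genes_", s)]]),
                     sum(all_df$species == s))
  }
  expect_error(sharing_report(all_df[all_df$species == "sich", ]),
               ">= 2 species")
})

test_that("species with disjoint repertoires share no subfamilies", {
  set.seed(101)
  g1 <- data.frame(gene_id = sprintf("a%d", 1:4), species = "sp1",
                   protein = vapply(1:4, function(i) random_protein(100),
                                    character(1)),
                   stringsAsFactors = FALSE)
  g2 <- data.frame(gene_id = sprintf("b%d", 1:4), species = "sp2",
                   protein = vapply(1:4, function(i) random_protein(100),
                                    character(1)),
                   stringsAsFactors = FALSE)
  res <- cluster_subfamilies(rbind(g1, g2))
  rep <- sharing_report(res)
  expect_identical(sum(rep$combinations$n_species > 1), 0L)
})
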