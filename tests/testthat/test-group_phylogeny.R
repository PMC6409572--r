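# p-distances, neighbor joining, nearest-labeled-leaf group assignment,
# and Table-2-style group counts.

test_that("p-distances match a direct column-count oracle", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"],
               0.25)
  # gapped columns are skipped pairwise
  d <- p_distance_matrix(c(a = "AA-A", b = "AATT"))
  expect_equal(d["a", "b"], 1 / 3)
  set.seed(51)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    a <- strsplit(random_protein(n), "")[[1]]
    b <- strsplit(random_protein(n), "")[[1]]
    gaps <- sample(n, 5)
    a[gaps[1:2]] <- "-"
    b[gaps[3:4]] <- "-"
    ok <- a != "-" & b != "-"
    oracle <- sum(a[ok] != b[ok]) / sum(ok)
    d <- p_distance_matrix(c(x = paste(a, collapse = ""),
                             y = paste(b, collapse = "")))
    expect_equal(d["x", "y"], oracle)
  }
  expect_error(p_distance_matrix(c(a = "AAA")), ">= 2")
})

test_that("neighbor joining recovers additive and ultrametric trees", {
  # 4-taxon additive matrix from ((A:1,B:2):1,(C:3,D:4))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tree <- build_nj_tree(d)
  # the AB|CD split must be present
  expect_true(ape::is.monophyletic(ape::root(tree, "C"), c("A", "B")))
  expect_equal(unname(ape::cophenetic.phylo(tree)["A", "B"]), 3)
  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- build_nj_tree(d3)
  pd <- ape::cophenetic.phylo(t3)
  expect_equal(unname(pd["x", "y"]), 2)
  expect_equal(unname(pd["x", "z"]), 3)
  expect_equal(unname(pd["y", "z"]), 5)
  # consistency on random additive matrices
  set.seed(61)
  for (i in 1:50) {
    ref <- ape::rtree(6)
    dm <- ape::cophenetic.phylo(ref)
    rec <- build_nj_tree(dm)
    expect_identical(as.integer(ape::dist.topo(ape::unroot(ref), rec)),
                     0L)
  }
  # ultrametric 8-taxon tree
  for (i in 1:5) {
    ref <- ape::rcoal(8)
    rec <- build_nj_tree(ape::cophenetic.phylo(ref))
    expect_identical(as.integer(ape::dist.topo(ape::unroot(ref), rec)),
                     0L)
  }
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(build_nj_tree(bad), "symmetric|taxa")
})

test_that("negative NJ branch lengths are clamped preserving sisters", {
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0),
              4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- build_nj_tree(d)
  expect_true(all(tree$edge.length >= 0))
})

test_that("labeled references recover their own group (self-assignment)", {
  sim <- tiny_sim()
  panel <- sim$panels$references
  res <- assign_groups(panel$or, panel, bootstrap_reps = 0)
  expect_identical(res$group_label,
                   unname(panel$or_groups[res$gene_id]))
  # theta references flag non-OR
  expect_true(all(res$non_or[res$group_label == "theta"]))
  expect_false(any(res$non_or[res$group_label != "theta"]))
})

test_that("planted genes are assigned their planted group", {
  sim <- tiny_sim()
  run <- tiny_run()
  ev <- evaluate_recovery(run$models, sim$truth)
  map <- setNames(ev$per_gene$gene_id, ev$per_gene$model_id)
  truth_grp <- sim$truth$group_label[
    match(map[run$assignments$gene_id], sim$truth$gene_id)]
  expect_identical(run$assignments$group_label, truth_grp)
})

test_that("equidistant queries resolve to the smallest group label", {
  refs <- c(r1 = "MKKWWCCHHDDEEKKRR", r2 = "MKKWWCCHHDDEEKKRR")
  panel <- list(or = refs, or_groups = c(r1 = "eta", r2 = "beta"))
  res <- assign_groups(c(q = "MKKWWCCHHDDEEKKRR"), panel,
                       bootstrap_reps = 0)
  expect_identical(res$group_label, "beta")
})

test_that("group counts format functional(pseudo) cells and conserve totals", {
  assignments <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    group_label = c(rep("delta", 5), rep("zeta", 2), rep("eta", 2),
                    "theta"),
    non_or = c(rep(FALSE, 9), TRUE), stringsAsFactors = FALSE)
  statuses <- setNames(c(rep("functional", 4), "pseudogene",
                         "functional", "pseudogene", rep("functional", 2),
                         "functional"), assignments$gene_id)
  tab <- group_count_table(assignments, statuses, species = "synthetic")
  expect_identical(tab$delta, "4(1)")
  expect_identical(tab$zeta, "1(1)")
  expect_identical(tab$eta, "2")     # (0) suppressed
  expect_identical(tab$non_or, "1")
  expect_identical(tab$total, "7(2)")
  parsed <- parse_count_cell(c(tab$delta, tab$zeta, tab$eta))
  expect_identical(sum(parsed[, "functional"]) + 1L +
                     sum(parsed[, "pseudo"]),
                   nrow(assignments))
})

test_that("pooling published Percomorpha counts gives the combined total", {
  tbl <- read_tsv_report(system.file("extdata",
                                     "percomorpha_group_counts.tsv",
                                     package = "orminer"))
  expect_identical(pool_functional_counts(tbl), 499L)
  # the Chinese perch row's pseudogene components sum to its total
  row <- tbl[tbl$species == "Chinese_perch", ]
  per_group <- parse_count_cell(unlist(
    row[c("beta", "delta", "zeta", "eta")]))
  expect_identical(sum(per_group[, "pseudo"]), 29L)
})
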