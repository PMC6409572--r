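# Group assignment: star alignment to the longest reference, protein
# p-distances, a neighbor-joining tree over queries plus labeled
# references, and nearest-labeled-leaf group calls with bootstrap support.

OR_GROUP_LABELS <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                     "eta", "theta", "kappa", "lambda")
NON_OR_GROUPS <- c("theta", "kappa", "lambda")

#' Star alignment anchored on the longest sequence
#'
#' Aligns every sequence globally to the anchor (BLOSUM62, gap open 11 /
#' extend 1) and projects it onto the anchor's columns; insertions relative
#' to the anchor are dropped. Deterministic and adequate for p-distance
#' classification.
#'
#' @param proteins named protein character vector or `AAStringSet`.
#' @param anchor anchor id; default the longest sequence (ties: first).
#' @return character matrix, one row per sequence, `nchar(anchor)` columns.
#' @export
star_align <- function(proteins, anchor = NULL) {
  proteins <- unlist(as_named_character(proteins))
  if (length(proteins) < 2) stop("star alignment needs >= 2 sequences")
  if (is.null(anchor)) anchor <- names(proteins)[which.max(nchar(proteins))]
  anchor_seq <- proteins[[anchor]]
  ncol <- nchar(anchor_seq)
  mat <- matrix("-", nrow = length(proteins), ncol = ncol,
                dimnames = list(names(proteins), NULL))
  mat[anchor, ] <- strsplit(anchor_seq, "")[[1]]
  b62 <- blosum62()
  for (nm in setdiff(names(proteins), anchor)) {
    # ends-free alignment so N/C-terminally truncated sequences keep their
    # register against the anchor; unaligned anchor ends become gaps
    al <- Biostrings::pairwiseAlignment(
      proteins[[nm]], anchor_seq, substitutionMatrix = b62,
      gapOpening = 11, gapExtension = 1, type = "overlap")
    pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sbj <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    keep <- sbj != "-"
    row <- pat[keep]
    from <- Biostrings::start(Biostrings::subject(al))
    stopifnot(from + length(row) - 1 <= ncol)
    mat[nm, seq(from, from + length(row) - 1)] <- row
  }
  mat
}

#' Pairwise p-distance matrix from aligned proteins
#'
#' `d(i, j)` is the fraction of mismatching residues over columns where
#' neither row has a gap; columns with a gap in either row are skipped.
#'
#' @param aligned character matrix (rows = sequences) or equal-length named
#'   character vector of aligned rows.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aligned) {
  if (is.character(aligned) && is.null(dim(aligned))) {
    stopifnot(length(unique(nchar(aligned))) == 1)
    nm <- names(aligned)
    aligned <- do.call(rbind, strsplit(aligned, ""))
    rownames(aligned) <- nm
  }
  n <- nrow(aligned)
  if (n < 2) stop("p-distance needs >= 2 sequences")
  gap <- aligned == "-"
  d <- matrix(0, n, n, dimnames = list(rownames(aligned),
                                       rownames(aligned)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      ncomp <- sum(ok)
      d[i, j] <- d[j, i] <- if (ncomp == 0) NA_real_ else
        sum(aligned[i, ok] != aligned[j, ok]) / ncomp
    }
  }
  d
}

#' Build an unrooted neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) with one postprocessing
#' step: negative branch lengths are clamped to zero and the deficit moved
#' to the sister branch, preserving path lengths through the parent.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return an unrooted [ape::phylo] tree.
#' @export
build_nj_tree <- function(d) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (nrow(d) < 3) stop("neighbor joining needs >= 3 taxa")
  tree <- ape::nj(d)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == parent)
    sib <- setdiff(sib, e)
    if (length(sib) > 0)
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
  }
  tree
}

#' Assign query proteins to OR groups by nearest labeled tree leaf
#'
#' Queries and labeled references are star-aligned, a p-distance NJ tree is
#' built over all of them, and each query takes the group of its nearest
#' labeled reference leaf by tree path length (ties: smallest group label,
#' flagged low support). Bootstrap support is the fraction of
#' column-resampling replicates agreeing with the point assignment.
#' Assignments to theta/kappa/lambda are flagged non-OR.
#'
#' @param query_proteins named protein vector.
#' @param panel a [reference_panel()] (its labeled OR side is used) or a
#'   list with `or` (named proteins) and `or_groups`.
#' @param bootstrap_reps bootstrap replicates (default 100; 0 disables).
#' @param seed seed for the bootstrap resampling.
#' @return data.frame: gene_id, group_label, support (path distance to the
#'   nearest labeled leaf), bootstrap, non_or.
#' @export
assign_groups <- function(query_proteins, panel, bootstrap_reps = 100,
                          seed = 1L) {
  queries <- unlist(as_named_character(query_proteins))
  refs <- unlist(as_named_character(panel$or))
  groups <- setNames(as.character(panel$or_groups), names(refs))
  if (!all(groups %in% OR_GROUP_LABELS))
    stop("unknown group label(s): ",
         paste(setdiff(groups, OR_GROUP_LABELS), collapse = ", "))
  qnames <- paste0("q::", names(queries))
  all_seq <- c(setNames(queries, qnames), refs)
  # anchor on the longest labeled reference: queries may be truncated or
  # frameshift-damaged and would make unstable anchors
  anchor <- names(refs)[which.max(nchar(refs))]
  aligned <- star_align(all_seq, anchor = anchor)

  assign_once <- function(cols) {
    sub <- aligned[, cols, drop = FALSE]
    usable <- rowSums(sub != "-") > 0
    d <- p_distance_matrix(sub[usable, , drop = FALSE])
    # sequence pairs sharing no gap-free column (e.g. opposite-end
    # truncations) are maximally distant
    d[is.na(d)] <- 1
    tree <- build_nj_tree(d)
    pd <- ape::cophenetic.phylo(tree)
    ref_tips <- intersect(rownames(pd), names(refs))
    res <- lapply(qnames, function(qn) {
      if (!(qn %in% rownames(pd)))
        return(list(group = NA_character_, support = NA_real_))
      dq <- pd[qn, ref_tips]
      if (anyNA(dq)) dq <- dq[!is.na(dq)]
      best <- min(dq)
      cand <- sort(groups[names(dq)[dq <= best + 1e-12]])
      list(group = cand[[1]], support = best)
    })
    setNames(res, qnames)
  }

  point <- assign_once(seq_len(ncol(aligned)))
  unassigned <- vapply(point, function(x) is.na(x$group), logical(1))
  for (qn in qnames[unassigned])
    or_log("assign-groups", qn, " unassigned (no aligned columns)")

  boot <- rep(NA_real_, length(qnames))
  if (bootstrap_reps > 0) {
    set.seed(seed)
    agree <- matrix(FALSE, nrow = bootstrap_reps, ncol = length(qnames))
    for (b in seq_len(bootstrap_reps)) {
      cols <- sample.int(ncol(aligned), replace = TRUE)
      rep_assign <- assign_once(cols)
      agree[b, ] <- vapply(seq_along(qnames), function(i) {
        identical(rep_assign[[qnames[i]]]$group, point[[qnames[i]]]$group)
      }, logical(1))
    }
    boot <- colMeans(agree)
  }

  grp <- vapply(point, function(x) x$group, character(1))
  data.frame(
    gene_id = names(queries),
    group_label = grp,
    support = vapply(point, function(x) x$support, numeric(1)),
    bootstrap = boot,
    non_or = !is.na(grp) & grp %in% NON_OR_GROUPS,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Group count table (functional genes with pseudogenes in parentheses)
#'
#' One row per species with per-group cells formatted `n` or `n(p)` (the
#' `(0)` suppressed), a Non-OR column (theta/kappa/lambda assignments), and
#' a Total column.
#'
#' @param assignments data.frame with `gene_id`, `group_label`, optionally
#'   `species`.
#' @param statuses named status vector (or data.frame with `gene_id`,
#'   `status`).
#' @param species optional species label(s) if not in `assignments`.
#' @return data.frame of formatted counts, one row per species.
#' @export
group_count_table <- function(assignments, statuses, species = NULL) {
  if (is.data.frame(statuses))
    statuses <- setNames(statuses$status, statuses$gene_id)
  df <- assignments
  df$status <- statuses[df$gene_id]
  df$species <- if (!is.null(df$species)) df$species
    else if (!is.null(species)) species else "this_study"
  fmt <- function(f, p) ifelse(p > 0, sprintf("%d(%d)", f, p),
                               sprintf("%d", f))
  or_groups <- setdiff(OR_GROUP_LABELS, NON_OR_GROUPS)
  rows <- lapply(split(df, df$species), function(sub) {
    cells <- lapply(or_groups, function(g) {
      sel <- sub$group_label == g & !sub$non_or
      fmt(sum(sel & sub$status == "functional", na.rm = TRUE),
          sum(sel & sub$status == "pseudogene", na.rm = TRUE))
    })
    non_or_n <- sum(sub$non_or, na.rm = TRUE)
    tot_f <- sum(!sub$non_or & sub$status == "functional", na.rm = TRUE)
    tot_p <- sum(!sub$non_or & sub$status == "pseudogene", na.rm = TRUE)
    c(list(species = sub$species[1]), setNames(cells, or_groups),
      list(non_or = as.character(non_or_n), total = fmt(tot_f, tot_p)))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Parse `n(p)` count cells from a group count table
#'
#' @param x character vector of cells like `"74(13)"` or `"8"`.
#' @return matrix with columns `functional` and `pseudo`.
#' @export
parse_count_cell <- function(x) {
  f <- as.integer(sub("\\(.*$", "", x))
  p <- ifelse(grepl("\\(", x),
              as.integer(sub("^.*\\((\\d+)\\).*$", "\\1", x)), 0L)
  cbind(functional = f, pseudo = p)
}

#' Pool functional-gene counts across species rows
#'
#' Sums the functional component of the `total` column of a group count
#' table (as written by [group_count_table()] or shipped as TSV) over the
#' selected species.
#'
#' @param tbl data.frame with `species` and `total` columns.
#' @param species species to pool; default all rows.
#' @return integer pooled functional-gene count.
#' @export
pool_functional_counts <- function(tbl, species = NULL) {
  if (!is.null(species)) tbl <- tbl[tbl$species %in% species, , drop = FALSE]
  sum(parse_count_cell(tbl$total)[, "functional"])
}
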