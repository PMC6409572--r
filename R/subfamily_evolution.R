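# Subfamily evolution: pairwise protein identity, single-linkage
# clustering into families (40%) and subfamilies (60%), and cross-species
# sharing reports.

#' Global percent identity between two proteins
#'
#' Global alignment with BLOSUM62 (gap open 11 / extend 1) and free
#' terminal gaps; identity is identities over alignment columns excluding
#' terminal-gap columns, times 100. Symmetric by construction.
#'
#' @param a,b protein strings.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  # canonical argument order: among co-optimal alignments the traceback
  # depends on pattern/subject roles, so fix the roles for exact symmetry
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  al <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = blosum62(), gapOpening = 11,
    gapExtension = 1, type = "overlap")
  100 * Biostrings::nmatch(al) / Biostrings::nchar(al)
}

identity_matrix <- function(proteins) {
  n <- length(proteins)
  m <- matrix(100, n, n, dimnames = list(names(proteins), names(proteins)))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- pairwise_identity(proteins[[i]], proteins[[j]])
    }
  }
  m
}

# Partition gene ids into clusters of mutual identity >= cutoff.
# single linkage: connected components of the >= cutoff graph;
# complete linkage: hclust on (100 - identity), cut at 100 - cutoff.
cluster_at <- function(idm, cutoff, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  ids <- rownames(idm)
  if (linkage == "single") {
    g <- igraph::graph_from_adjacency_matrix(idm >= cutoff,
                                             mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
  } else {
    if (length(ids) == 1) {
      comp <- setNames(1L, ids)
    } else {
      hc <- stats::hclust(stats::as.dist(100 - idm), method = "complete")
      comp <- stats::cutree(hc, h = 100 - cutoff)
    }
  }
  split(ids, comp)
}

#' Cluster functional OR proteins into families and subfamilies
#'
#' Genes join one subfamily when linked by pairwise protein identity at or
#' above `subfamily_cutoff` (default 60%), and one family at
#' `family_cutoff` (default 40%); the subfamily partition refines the
#' family partition. Cluster ids are named after the smallest member gene
#' id, so partitions are invariant to input order.
#'
#' @param genes data.frame with `gene_id`, `species`, `protein`
#'   (functional genes only).
#' @param subfamily_cutoff,family_cutoff percent-identity cutoffs in
#'   `(0, 100]`; membership uses `>=`.
#' @param linkage `"single"` (default) or `"complete"`.
#' @return data.frame: gene_id, species, family_id, subfamily_id.
#' @export
cluster_subfamilies <- function(genes, subfamily_cutoff = 60,
                                family_cutoff = 40,
                                linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  for (cutoff in c(subfamily_cutoff, family_cutoff)) {
    if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 100)
      stop("identity cutoff must lie in (0, 100]")
  }
  stopifnot(all(c("gene_id", "species", "protein") %in% names(genes)),
            !anyDuplicated(genes$gene_id))
  prot <- setNames(genes$protein, genes$gene_id)
  prot <- prot[order(names(prot))]
  idm <- identity_matrix(prot)
  subfams <- cluster_at(idm, subfamily_cutoff, linkage)
  fams <- cluster_at(idm, family_cutoff, linkage)
  name_of <- function(members, prefix)
    paste0(prefix, ".", sort(members)[1])
  sub_id <- character(0)
  for (m in subfams) sub_id[m] <- name_of(m, "SF")
  fam_id <- character(0)
  for (m in fams) fam_id[m] <- name_of(m, "FAM")
  out <- data.frame(gene_id = genes$gene_id, species = genes$species,
                    family_id = unname(fam_id[genes$gene_id]),
                    subfamily_id = unname(sub_id[genes$gene_id]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-species subfamily sharing report
#'
#' Partitions subfamilies by the exact combination of species in which
#' they occur, reporting subfamily counts, per-species gene counts, and
#' integer-percent fractions of the subfamily total per combination.
#' Species-specific rows are the combinations of size one.
#'
#' @param assignments data.frame from [cluster_subfamilies()].
#' @return list with `combinations` (data.frame, one row per observed
#'   species combination), `species_specific` (subset of size-one rows),
#'   and `total_subfamilies`.
#' @export
sharing_report <- function(assignments) {
  species <- sort(unique(assignments$species))
  if (length(species) < 2) stop("sharing report needs >= 2 species")
  by_sf <- split(assignments, assignments$subfamily_id)
  total <- length(by_sf)
  combo_of <- vapply(by_sf, function(sf)
    paste(sort(unique(sf$species)), collapse = "+"), character(1))
  rows <- lapply(unique(combo_of), function(cm) {
    sfs <- by_sf[combo_of == cm]
    genes_per_species <- vapply(species, function(sp)
      sum(vapply(sfs, function(sf) sum(sf$species == sp), integer(1))),
      integer(1))
    n_sp <- length(strsplit(cm, "+", fixed = TRUE)[[1]])
    cbind(data.frame(combination = cm, n_species = n_sp,
                     n_subfamilies = length(sfs),
                     pct = as.integer(round_half_up(
                       100 * length(sfs) / total)),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(genes_per_species,
                                         paste0("genes_", species)))))
  })
  combos <- do.call(rbind, rows)
  combos <- combos[order(-combos$n_species, combos$combination), ,
                   drop = FALSE]
  rownames(combos) <- NULL
  list(combinations = combos,
       species_specific = combos[combos$n_species == 1, , drop = FALSE],
       total_subfamilies = total)
}

#' Fraction of subfamilies shared by exactly n species
#'
#' @param report output of [sharing_report()].
#' @param n_species combination size of interest.
#' @return integer percent (half-up) of the subfamily total.
#' @export
sharing_fraction <- function(report, n_species) {
  n <- sum(report$combinations$n_subfamilies[
    report$combinations$n_species == n_species])
  as.integer(round_half_up(100 * n / report$total_subfamilies))
}
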