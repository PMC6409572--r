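# Per-group dN/dS by the Nei-Gojobori (1986) counting method with
# Jukes-Cantor correction: synonymous site fractions per codon, multi-hit
# codon differences averaged over all minimal substitution paths (paths
# through stop codons excluded), and group means over pairwise ratios.

all_codons <- function() {
  nt <- c("T", "C", "A", "G")
  g <- expand.grid(p3 = nt, p2 = nt, p1 = nt,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

codon_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc[all_codons()]), all_codons())
}

# Precomputed NG86 tables: per-codon synonymous site counts and 64x64
# average (syn, nonsyn) difference counts over minimal substitution paths.
ng86_tables <- function() {
  if (!is.null(.orminer_env$ng86)) return(.orminer_env$ng86)
  codons <- all_codons()
  aa <- codon_aa()
  nt <- c("T", "C", "A", "G")
  is_stop <- aa == "*"

  mutate1 <- function(codon, pos, base) {
    s <- strsplit(codon, "")[[1]]
    s[pos] <- base
    paste(s, collapse = "")
  }
  # synonymous site count per codon: fraction of the 9 one-nt changes that
  # are synonymous, times 3 (changes to stop codons count nonsynonymous)
  syn_sites <- vapply(codons, function(c0) {
    if (is_stop[c0]) return(NA_real_)
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(nt, substr(c0, pos, pos))) {
        c1 <- mutate1(c0, pos, b)
        if (!is_stop[c1] && aa[c1] == aa[c0]) syn <- syn + 1
      }
    }
    3 * syn / 9
  }, numeric(1))

  # average per-pair (syn, nonsyn) difference counts over minimal paths
  path_counts <- function(ca, cb) {
    diffs <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (length(diffs) == 0) return(c(0, 0))
    perms <- permutations_of(diffs)
    acc <- matrix(NA_real_, nrow = length(perms), ncol = 2)
    for (k in seq_along(perms)) {
      cur <- ca
      sd <- 0; nd <- 0; ok <- TRUE
      for (pos in perms[[k]]) {
        nxt <- mutate1(cur, pos, substr(cb, pos, pos))
        if (is_stop[nxt]) { ok <- FALSE; break }
        if (aa[nxt] == aa[cur]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) acc[k, ] <- c(sd, nd)
    }
    valid <- stats::complete.cases(acc)
    if (!any(valid)) {
      # all paths pass through stops: average over all paths, counting
      # steps into stops as nonsynonymous
      acc2 <- t(vapply(perms, function(perm) {
        cur <- ca; sd <- 0; nd <- 0
        for (pos in perm) {
          nxt <- mutate1(cur, pos, substr(cb, pos, pos))
          if (!is_stop[nxt] && aa[nxt] == aa[cur]) sd <- sd + 1
          else nd <- nd + 1
          cur <- nxt
        }
        c(sd, nd)
      }, numeric(2)))
      return(colMeans(acc2))
    }
    colMeans(acc[valid, , drop = FALSE])
  }

  sense <- codons[!is_stop]
  idx <- seq_along(sense)
  Sd <- matrix(0, length(sense), length(sense),
               dimnames = list(sense, sense))
  Nd <- Sd
  for (i in idx) {
    for (j in idx) {
      if (i < j) {
        pc <- path_counts(sense[i], sense[j])
        Sd[i, j] <- Sd[j, i] <- pc[1]
        Nd[i, j] <- Nd[j, i] <- pc[2]
      }
    }
  }
  .orminer_env$ng86 <- list(syn_sites = syn_sites[sense], Sd = Sd, Nd = Nd,
                            sense = sense, aa = aa)
  .orminer_env$ng86
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Each aligned protein row is mapped onto its coding sequence: residue
#' columns become codons, gap columns become `---` triplets. The CDS must
#' translate exactly to the degapped protein row (a trailing stop codon on
#' the CDS is tolerated and dropped).
#'
#' @param cds_set named character vector of coding sequences.
#' @param protein_alignment named character vector (or matrix rows) of
#'   equal-length aligned proteins.
#' @return character matrix of codons (rows = genes, columns = alignment
#'   positions).
#' @export
codon_align <- function(cds_set, protein_alignment) {
  if (is.matrix(protein_alignment)) {
    protein_alignment <- setNames(
      apply(protein_alignment, 1, paste, collapse = ""),
      rownames(protein_alignment))
  }
  stopifnot(length(unique(nchar(protein_alignment))) == 1)
  genes <- names(protein_alignment)
  ncol_aln <- nchar(protein_alignment[[1]])
  out <- matrix("---", nrow = length(genes), ncol = ncol_aln,
                dimnames = list(genes, NULL))
  for (g in genes) {
    cds <- cds_set[[g]]
    if (is.null(cds)) stop("no CDS for gene ", g)
    ncod <- nchar(cds) %/% 3
    codons <- substring(cds, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    if (codons[ncod] %in% STOP_CODONS) codons <- codons[-ncod]
    row <- strsplit(protein_alignment[[g]], "")[[1]]
    res_cols <- which(row != "-")
    if (length(res_cols) != length(codons))
      stop("CDS/protein length mismatch for gene ", g)
    aa <- codon_aa()[codons]
    if (!identical(unname(aa), row[res_cols]))
      stop("CDS does not translate to its protein row for gene ", g)
    out[g, res_cols] <- codons
  }
  out
}

#' Pairwise dN and dS by Nei-Gojobori (1986)
#'
#' Synonymous site counts are per-codon fractions of synonymous one-nt
#' changes; codons differing at several positions average their
#' synonymous/nonsynonymous difference counts over all minimal
#' substitution paths (paths through stop codons excluded). Proportions
#' are Jukes-Cantor corrected, `d = -3/4 log(1 - 4 p / 3)`; a proportion
#' at or beyond 3/4 is flagged saturated (`NA` distance).
#'
#' @param codons_a,codons_b aligned codon vectors (triplets, `---` for
#'   gaps); gap-containing columns are skipped pairwise.
#' @return list: `dN`, `dS`, `pN`, `pS`, site counts `N`/`S`, difference
#'   counts `Nd`/`Sd`, `saturated` flag, `ratio` (dN/dS, `NA` unless
#'   `dS > 0`).
#' @export
ng86_pair <- function(codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b))
  tab <- ng86_tables()
  gap <- codons_a == "---" | codons_b == "---"
  a <- codons_a[!gap]
  b <- codons_b[!gap]
  if (length(a) == 0) stop("no comparable codons")
  if (any(!(a %in% tab$sense)) || any(!(b %in% tab$sense))) {
    bad <- unique(c(a[!(a %in% tab$sense)], b[!(b %in% tab$sense)]))
    stop("stop or invalid codon in alignment: ",
         paste(bad, collapse = ", "))
  }
  S <- (sum(tab$syn_sites[a]) + sum(tab$syn_sites[b])) / 2
  N <- 3 * length(a) - S
  Sd <- sum(tab$Sd[cbind(a, b)])
  Nd <- sum(tab$Nd[cbind(a, b)])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS)
  dN <- jc(pN)
  ratio <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  list(dN = dN, dS = dS, pN = pN, pS = pS, N = N, S = S, Nd = Nd, Sd = Sd,
       saturated = is.na(dS) || is.na(dN), ratio = ratio)
}

#' Per-group average dN/dS
#'
#' For every group with at least two sequences, all pairwise NG86
#' estimates are computed on codon alignments back-translated from
#' pairwise global protein alignments, and averaged; the ratio is
#' averaged over pairs where it is defined (`dS > 0`, unsaturated). Groups where no pair yields a defined
#' ratio, and single-sequence groups, are excluded with a log message.
#' The group with the highest mean ratio is flagged.
#'
#' @param cds_set named coding sequences (no internal stops; pseudogenes
#'   are excluded upstream).
#' @param proteins named proteins matching `cds_set`.
#' @param groups named group labels per gene.
#' @return list with `groups` (data.frame: group_label, n_sequences,
#'   n_pairs, mean_dN, mean_dS, mean_ratio, highest) and `pairs` (per-pair
#'   table).
#' @export
group_average_dnds <- function(cds_set, proteins, groups) {
  proteins <- unlist(as_named_character(proteins))
  groups <- groups[names(proteins)]
  res_rows <- list()
  pair_rows <- list()
  b62 <- blosum62()
  for (g in sort(unique(groups))) {
    ids <- names(groups)[groups == g]
    if (length(ids) < 2) {
      or_log("dnds", "group ", g, " excluded: fewer than 2 sequences")
      next
    }
    pairs <- utils::combn(ids, 2)
    per_pair <- lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      # pairwise global protein alignment keeps every residue of both
      # sequences, so back-translation is always exact
      al <- Biostrings::pairwiseAlignment(
        proteins[[a]], proteins[[b]], substitutionMatrix = b62,
        gapOpening = 11, gapExtension = 1, type = "global")
      aln <- setNames(c(as.character(Biostrings::alignedPattern(al)),
                        as.character(Biostrings::alignedSubject(al))),
                      c(a, b))
      cal <- codon_align(cds_set[c(a, b)], aln)
      p <- ng86_pair(cal[a, ], cal[b, ])
      data.frame(group_label = g, gene_a = a,
                 gene_b = b, dN = p$dN, dS = p$dS,
                 ratio = p$ratio, saturated = p$saturated,
                 stringsAsFactors = FALSE)
    })
    pp <- do.call(rbind, per_pair)
    pair_rows[[g]] <- pp
    if (all(is.na(pp$ratio))) {
      or_log("dnds", "group ", g, " excluded: no defined dN/dS ratio")
      next
    }
    res_rows[[g]] <- data.frame(
      group_label = g, n_sequences = length(ids), n_pairs = nrow(pp),
      mean_dN = mean(pp$dN, na.rm = TRUE),
      mean_dS = mean(pp$dS, na.rm = TRUE),
      mean_ratio = mean(pp$ratio, na.rm = TRUE), stringsAsFactors = FALSE)
  }
  if (length(res_rows) == 0)
    return(list(groups = NULL, pairs = do.call(rbind, pair_rows)))
  gdf <- do.call(rbind, res_rows)
  gdf <- gdf[order(-gdf$mean_ratio), , drop = FALSE]
  gdf$highest <- seq_len(nrow(gdf)) == 1
  rownames(gdf) <- NULL
  list(groups = gdf, pairs = do.call(rbind, pair_rows))
}

#' Simulate codon-sequence pairs under a target dN/dS
#'
#' Each pair diverges from a random stop-free ancestor by `n_subs`
#' accepted substitutions: proposed single-nucleotide changes never create
#' a stop codon, synonymous proposals are always accepted, nonsynonymous
#' proposals are accepted with probability `omega`. The realized
#' nonsynonymous/synonymous rate ratio therefore approximates `omega`.
#'
#' @param n_pairs number of independent pairs.
#' @param n_codons codons per sequence.
#' @param n_subs accepted substitutions per pair.
#' @param omega target dN/dS.
#' @param seed integer seed.
#' @return list of pairs, each a list with codon vectors `a` and `b`.
#' @export
simulate_codon_pairs <- function(n_pairs, n_codons, n_subs, omega, seed) {
  set.seed(seed)
  tab <- ng86_tables()
  nt <- c("T", "C", "A", "G")
  out <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    anc <- sample(tab$sense, n_codons, replace = TRUE)
    der <- anc
    accepted <- 0
    while (accepted < n_subs) {
      i <- sample.int(n_codons, 1)
      pos <- sample.int(3, 1)
      old <- substr(der[i], pos, pos)
      new <- sample(setdiff(nt, old), 1)
      cand <- der[i]
      substr(cand, pos, pos) <- new
      if (tab$aa[cand] == "*") next
      syn <- tab$aa[cand] == tab$aa[der[i]]
      if (!syn && stats::runif(1) > omega) next
      der[i] <- cand
      accepted <- accepted + 1
    }
    out[[p]] <- list(a = anc, b = der)
  }
  out
}
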