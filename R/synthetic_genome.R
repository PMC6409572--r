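# Synthetic multi-contig genomes with planted OR-like genes (intact,
# pseudogenized, edge-truncated), non-OR GPCR decoys, i.i.d. background,
# and a machine-readable truth table. The generator's defaults define the
# study conditions every downstream stage is validated against.

HYDROPHOBIC_AA <- c("I", "L", "V", "F", "A")
HYDROPHILIC_AA <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "H",
                    "P", "Y")

#' Generator specification for a synthetic OR genome
#'
#' Defaults plant 40 functional genes, 12 pseudogenes and 8 edge-truncated
#' genes in 8 tandem clusters (2+2+2+1+1) across 5 contigs, plus 10 non-OR
#' GPCR decoys, with within-cluster spacing of 10 kb and an inter-cluster
#' gap of 1.2 Mb (the megabase rule requires > 1 Mb). The subfamily plan
#' lists, per subfamily, its group, member count and within-subfamily
#' percent-identity target (must exceed the 60% subfamily cutoff).
#'
#' @param n_contigs number of contigs.
#' @param contig_length_bp length of each contig in bp.
#' @param n_functional,n_pseudo,n_truncated,n_decoys planted gene counts.
#' @param cluster_gap_bp within-cluster spacing between adjacent genes.
#' @param intercluster_gap_bp gap separating planned clusters on one
#'   contig; must exceed 1 Mb.
#' @param subfamily_plan data.frame with `subfamily`, `group`,
#'   `n_members`, `identity_target` (functional genes; member counts must
#'   sum to `n_functional`).
#' @param gc_content background GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_contigs = 5,
                           contig_length_bp = 1600000,
                           n_functional = 40,
                           n_pseudo = 12,
                           n_truncated = 8,
                           n_decoys = 10,
                           cluster_gap_bp = 10000,
                           intercluster_gap_bp = 1200000,
                           subfamily_plan = default_subfamily_plan(),
                           gc_content = 0.41,
                           seed = 1L) {
  spec <- list(n_contigs = as.integer(n_contigs),
               contig_length_bp = as.integer(contig_length_bp),
               n_functional = as.integer(n_functional),
               n_pseudo = as.integer(n_pseudo),
               n_truncated = as.integer(n_truncated),
               n_decoys = as.integer(n_decoys),
               cluster_gap_bp = as.integer(cluster_gap_bp),
               intercluster_gap_bp = as.integer(intercluster_gap_bp),
               subfamily_plan = subfamily_plan,
               gc_content = gc_content,
               seed = as.integer(seed))
  counts <- c(spec$n_contigs, spec$n_functional, spec$n_pseudo,
              spec$n_truncated, spec$n_decoys)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (spec$intercluster_gap_bp <= 1e6)
    stop("intercluster_gap_bp must exceed 1,000,000")
  if (any(subfamily_plan$identity_target <= 60 |
            subfamily_plan$identity_target > 100))
    stop("within-subfamily identity targets must lie in (60, 100]")
  if (sum(subfamily_plan$n_members) != spec$n_functional)
    stop("subfamily plan member counts must sum to n_functional")
  if (gc_content < 0 || gc_content > 1)
    stop("gc_content must lie in [0, 1]")
  class(spec) <- "generator_spec"
  spec
}

#' @rdname generator_spec
#' @export
default_subfamily_plan <- function() {
  data.frame(
    subfamily = c("d1", "d2", "d3", "h1", "h2", "z1", "e1", "b1"),
    group = c("delta", "delta", "delta", "eta", "eta", "zeta",
              "epsilon", "beta"),
    n_members = c(10L, 5L, 3L, 5L, 3L, 6L, 4L, 4L),
    identity_target = c(85, 75, 70, 80, 70, 75, 80, 80),
    stringsAsFactors = FALSE)
}

#' A small generator preset for fast exploratory runs
#'
#' Two short contigs, one cluster each; useful for examples and quick
#' checks. The scientific defaults live in [generator_spec()].
#'
#' @param seed integer seed.
#' @return a `generator_spec`.
#' @export
tiny_generator_spec <- function(seed = 1L) {
  plan <- data.frame(
    subfamily = c("d1", "h1", "b1"),
    group = c("delta", "eta", "beta"),
    n_members = c(4L, 3L, 2L),
    identity_target = c(80, 75, 80), stringsAsFactors = FALSE)
  generator_spec(n_contigs = 2, contig_length_bp = 150000,
                 n_functional = 9, n_pseudo = 3, n_truncated = 2,
                 n_decoys = 3, cluster_gap_bp = 8000,
                 intercluster_gap_bp = 1100000, subfamily_plan = plan,
                 seed = seed)
}

# ---- protein scaffolds -----------------------------------------------------

# Seven hydrophobic transmembrane stretches alternating with hydrophilic
# loops; the five configured motifs and one N-X-S/T sequon sit in loops at
# fixed scaffold slots so that mutation never destroys them. Met occurs
# only at position 1 (mutation alphabets exclude it), so edge-truncated
# copies cannot regain a start codon.
or_scaffold_layout <- function(motifs, rng_loop_extra) {
  loop <- function(n) list(kind = "loop", len = n)
  tm <- function() list(kind = "tm", len = 23)
  fixed <- function(s) list(kind = "fixed", seq = s)
  list(fixed("M"), loop(8), fixed("NGS"), loop(4), fixed(motifs[["I"]]),
       tm(), loop(6), fixed(motifs[["II"]]), loop(4),
       tm(), loop(14 + rng_loop_extra[1]),
       tm(), loop(5), fixed(motifs[["III"]]), loop(5),
       tm(), loop(14 + rng_loop_extra[2]),
       tm(), loop(5), fixed(motifs[["IV"]]), loop(5),
       tm(), loop(14 + rng_loop_extra[3]),
       tm(), loop(4), fixed(motifs[["V"]]), loop(12))
}

DECOY_MOTIFS <- c(I = "DWENQKSYH", II = "HRSTEDNQY", III = "QQHDYSPRT",
                  IV = "GEDKHNRTS", V = "YTNDQHKSE")

# Build a founder protein as (chars, mask) where mask is "fixed", "loop"
# or "tm"; loop/tm positions are mutable within their alphabet.
build_founder <- function(motif_strings, seed) {
  set.seed(seed)
  extra <- sample(0:6, 3, replace = TRUE)
  layout <- or_scaffold_layout(motif_strings, extra)
  chars <- character(0)
  mask <- character(0)
  for (el in layout) {
    if (el$kind == "fixed") {
      s <- strsplit(el$seq, "")[[1]]
      chars <- c(chars, s)
      mask <- c(mask, rep("fixed", length(s)))
    } else if (el$kind == "loop") {
      chars <- c(chars, sample(HYDROPHILIC_AA, el$len, replace = TRUE))
      mask <- c(mask, rep("loop", el$len))
    } else {
      chars <- c(chars, sample(HYDROPHOBIC_AA, el$len, replace = TRUE))
      mask <- c(mask, rep("tm", el$len))
    }
  }
  list(chars = chars, mask = mask)
}

group_founder <- function(group_label, base_seed = 20190225L) {
  idx <- match(group_label, OR_GROUP_LABELS)
  if (is.na(idx)) stop("unknown group label: ", group_label)
  cons <- vapply(default_motif_set(), `[[`, character(1), "pattern")
  build_founder(cons, seed = base_seed + idx)
}

decoy_founder <- function(idx, base_seed = 20190225L) {
  build_founder(DECOY_MOTIFS, seed = base_seed + 100L + idx)
}

# Point-mutate mutable positions at per-site rate, respecting alphabets.
mutate_protein <- function(obj, rate) {
  chars <- obj$chars
  hit <- which(obj$mask != "fixed" & stats::runif(length(chars)) < rate)
  for (i in hit) {
    alphabet <- if (obj$mask[i] == "tm") HYDROPHOBIC_AA else HYDROPHILIC_AA
    chars[i] <- sample(alphabet, 1)
  }
  list(chars = chars, mask = obj$mask)
}

protein_string <- function(obj) paste(obj$chars, collapse = "")

#' Generate one OR-like protein of a given group
#'
#' Mutates the deterministic group founder at a moderate per-site rate.
#' The output satisfies the generator contract: length at least 300
#' residues, at least seven transmembrane segments detectable by
#' [predict_tm_segments()], all five default motifs, and at least one
#' N-X-S/T sequon.
#'
#' @param group_label one of the configured group labels (alpha..lambda).
#' @param seed integer seed; identical inputs give identical proteins.
#' @param rate per-site mutation rate away from the group founder.
#' @return protein string.
#' @export
make_or_like_protein <- function(group_label, seed, rate = 0.15) {
  founder <- group_founder(group_label)
  set.seed(seed + 7919L * match(group_label, OR_GROUP_LABELS))
  protein_string(mutate_protein(founder, rate))
}

# Calibrate the member mutation rate so that two independently mutated
# subfamily members reach the target pairwise identity (binary search
# against pairwise_identity).
calibrate_member_rate <- function(subfounder, target_pct, seed) {
  lo <- 0.0; hi <- 0.6
  for (iter in 1:10) {
    mid <- (lo + hi) / 2
    set.seed(seed + iter)
    a <- protein_string(mutate_protein(subfounder, mid))
    b <- protein_string(mutate_protein(subfounder, mid))
    idt <- pairwise_identity(a, b)
    if (idt > target_pct) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ---- coding sequences ------------------------------------------------------

aa_codon_table <- function() {
  if (is.null(.orminer_env$aa_codons)) {
    gc <- Biostrings::GENETIC_CODE
    .orminer_env$aa_codons <- split(names(gc), unname(gc))
  }
  .orminer_env$aa_codons
}

# Uniform synonymous codon choice; a random stop codon terminates the CDS.
reverse_translate <- function(protein) {
  tab <- aa_codon_table()
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste0(paste(codons, collapse = ""),
         sample(STOP_CODONS, 1))
}

# Derive a child CDS from its parent's codons: positions where the amino
# acid is conserved inherit the parent codon (resampled synonymously at
# rate syn_rate); changed positions draw a uniform codon of the new amino
# acid. Keeps synonymous divergence realistic within a lineage instead of
# randomizing it.
inherit_codons <- function(parent_codons, parent_chars, child_chars,
                           syn_rate = 0.1) {
  tab <- aa_codon_table()
  stopifnot(length(parent_codons) == length(child_chars))
  vapply(seq_along(child_chars), function(i) {
    if (child_chars[i] == parent_chars[i] &&
        stats::runif(1) >= syn_rate) return(parent_codons[i])
    opts <- tab[[child_chars[i]]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
}

cds_codons <- function(cds) {
  ncod <- nchar(cds) %/% 3
  substring(cds, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
}

check_intact_orf <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length must be a multiple of 3")
  ncod <- n %/% 3
  codons <- substring(cds, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
  if (codons[1] != "ATG") stop("CDS must start with ATG")
  if (!(codons[ncod] %in% STOP_CODONS)) stop("CDS must end with a stop")
  if (any(codons[-ncod] %in% STOP_CODONS))
    stop("CDS contains an internal stop")
  codons
}

#' Disrupt an intact CDS into a pseudogene
#'
#' `mode = "stop"` replaces an interior codon (before the final 50) with a
#' random stop codon; `mode = "frameshift"` deletes one nucleotide (a
#' frameshift, k mod 3 != 0) downstream of the start codon; `"both"`
#' applies a stop at about one third and a frameshift at about two thirds
#' of the CDS. The start codon is always retained. Coding sequences
#' shorter than 250 codons are refused, since the disrupted model must
#' still meet the pseudogene length criterion.
#'
#' @param cds intact coding sequence (ATG..stop, no internal stops).
#' @param mode `"stop"`, `"frameshift"`, or `"both"`.
#' @param seed integer seed.
#' @return list: `cds` (disrupted), `disruptions` (list of
#'   `kind`/`codon_index`, 0-based codon indices).
#' @export
pseudogenize <- function(cds, mode = c("stop", "frameshift", "both"),
                         seed = 1L) {
  mode <- match.arg(mode)
  codons <- check_intact_orf(cds)
  ncod <- length(codons)
  if (ncod < 250) stop("CDS shorter than 250 codons: cannot pseudogenize")
  set.seed(seed)
  disruptions <- list()
  if (mode %in% c("stop", "both")) {
    at <- if (mode == "both") max(10L, round(ncod / 3)) else
      sample(seq(10L, ncod - 51L), 1)
    codons[at] <- sample(STOP_CODONS, 1)
    disruptions[[length(disruptions) + 1]] <-
      list(kind = "stop", codon_index = at - 1L)
  }
  out <- paste(codons, collapse = "")
  if (mode %in% c("frameshift", "both")) {
    at <- if (mode == "both") max(20L, round(2 * ncod / 3)) else
      sample(seq(10L, ncod - 51L), 1)
    nt_pos <- 3L * (at - 1L) + 1L
    out <- paste0(substr(out, 1, nt_pos - 1),
                  substr(out, nt_pos + 1, nchar(out)))
    disruptions[[length(disruptions) + 1]] <-
      list(kind = "frameshift", codon_index = at - 1L)
  }
  list(cds = out, disruptions = disruptions)
}

# Remove whole codons from one end: "start" drops the ATG end, "stop"
# drops the stop end. The fragment stays in frame.
truncate_cds <- function(cds, missing = c("start", "stop"),
                         n_codons = 60L) {
  missing <- match.arg(missing)
  codons <- check_intact_orf(cds)
  keep <- if (missing == "start") {
    codons[-seq_len(n_codons)]
  } else {
    codons[seq_len(length(codons) - n_codons)]
  }
  paste(keep, collapse = "")
}

# ---- genome assembly -------------------------------------------------------

default_cluster_layout <- function(n_contigs) {
  # (contig, slot, strand, truncation edge) for the default 8-cluster plan;
  # smaller/larger contig counts scale the same pattern.
  if (n_contigs >= 5) {
    data.frame(
      contig = c(1, 1, 2, 2, 3, 3, 4, 5),
      strand = c("+", "+", "-", "-", "+", "-", "+", "-"),
      edge = c("left", "right", "left", "right", "left", "right",
               "right", "left"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(contig = seq_len(n_contigs),
               strand = rep(c("+", "-"), length.out = n_contigs),
               edge = rep(c("left", "right"), length.out = n_contigs),
               stringsAsFactors = FALSE)
  }
}

#' Assemble a synthetic genome with planted ground truth
#'
#' Generates i.i.d. background at the requested GC content, plants OR-like
#' genes in tandem clusters (same strand within a cluster, more than 1 Mb
#' between clusters on one contig), pseudogenizes and edge-truncates the
#' planned subsets, scatters non-OR GPCR decoys far from the clusters, and
#' returns the contigs, a truth table, and the query/reference/decoy
#' panels the mining pipeline needs. An in-frame stop codon is planted
#' immediately upstream of each intact gene's ATG (stop-rich intergenic
#' DNA), which pins ORF rescue to the planted start.
#'
#' @param spec a [generator_spec()].
#' @return list: `contigs` ([Biostrings::DNAStringSet]), `truth`
#'   (data.frame), `gene_seqs` (planted strand-space sequences), `panels`
#'   (list with `queries` and `references`, a [reference_panel()]),
#'   `n_clusters_planned`, `spec`.
#' @export
assemble_genome <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)

  plan <- spec$subfamily_plan
  groups_used <- unique(plan$group)

  # group founder coding sequences (codons inherited down the lineage so
  # synonymous sites diverge gradually, not at random)
  set.seed(spec$seed + 3)
  group_cds <- lapply(setNames(groups_used, groups_used), function(g)
    cds_codons(reverse_translate(protein_string(group_founder(g)))))

  # subfamily founders and calibrated member rates
  subfounders <- list()
  subfounder_codons <- list()
  member_rate <- numeric(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    founder <- group_founder(plan$group[i])
    set.seed(spec$seed + 131L * i)
    sf <- mutate_protein(founder, 0.22)
    subfounders[[plan$subfamily[i]]] <- sf
    gcod <- group_cds[[plan$group[i]]]
    subfounder_codons[[plan$subfamily[i]]] <- inherit_codons(
      gcod[-length(gcod)], founder$chars, sf$chars)
    member_rate[i] <- calibrate_member_rate(
      subfounders[[plan$subfamily[i]]], plan$identity_target[i],
      seed = spec$seed + 977L * i)
  }
  make_member_cds <- function(i) {
    sf <- subfounders[[plan$subfamily[i]]]
    member <- mutate_protein(sf, member_rate[i])
    codons <- inherit_codons(subfounder_codons[[plan$subfamily[i]]],
                             sf$chars, member$chars)
    paste0(paste(codons, collapse = ""), sample(STOP_CODONS, 1))
  }

  # gene roster: functional members per subfamily, then pseudogenes and
  # truncated genes drawn from the same subfamilies (round-robin)
  set.seed(spec$seed + 5)
  roster <- list()
  add_gene <- function(id, status, group, subfam, cds, mode = NA,
                       missing = NA, disruptions = list()) {
    roster[[length(roster) + 1]] <<- list(
      gene_id = id, status = status, group = group, subfamily = subfam,
      cds = cds, mode = mode, missing = missing, disruptions = disruptions)
  }
  k <- 0
  for (i in seq_len(nrow(plan))) {
    for (m in seq_len(plan$n_members[i])) {
      k <- k + 1
      add_gene(sprintf("F%03d", k), "functional", plan$group[i],
               plan$subfamily[i], make_member_cds(i))
    }
  }
  rr <- rep(seq_len(nrow(plan)), length.out = spec$n_pseudo)
  modes <- rep(c("stop", "frameshift", "both"),
               length.out = spec$n_pseudo)
  for (j in seq_len(spec$n_pseudo)) {
    i <- rr[j]
    intact <- make_member_cds(i)
    ps <- pseudogenize(intact, modes[j], seed = spec$seed + 313L * j)
    add_gene(sprintf("P%03d", j), "pseudogene", plan$group[i],
             plan$subfamily[i], ps$cds, mode = modes[j],
             disruptions = ps$disruptions)
  }
  layout <- default_cluster_layout(spec$n_contigs)
  n_clusters <- nrow(layout)
  trunc_rows <- rep(seq_len(n_clusters),
                    length.out = spec$n_truncated)
  rrt <- rep(seq_len(nrow(plan)), length.out = spec$n_truncated)
  trunc_genes <- list()
  for (j in seq_len(spec$n_truncated)) {
    i <- rrt[j]
    row <- layout[trunc_rows[j], ]
    missing <- if ((row$edge == "left") == (row$strand == "+"))
      "start" else "stop"
    frag <- truncate_cds(make_member_cds(i), missing)
    trunc_genes[[j]] <- list(
      gene_id = sprintf("T%03d", j), status = "truncated",
      group = plan$group[i], subfamily = plan$subfamily[i], cds = frag,
      mode = NA, missing = missing, cluster = trunc_rows[j],
      edge = row$edge, disruptions = list())
  }

  # decoys
  decoys <- list()
  dec_founders <- lapply(1:3, decoy_founder)
  for (j in seq_len(spec$n_decoys)) {
    prot <- protein_string(mutate_protein(dec_founders[[1 + (j %% 3)]],
                                          0.10))
    decoys[[j]] <- list(gene_id = sprintf("D%03d", j), status = "decoy",
                        group = NA, subfamily = NA,
                        cds = reverse_translate(prot))
  }

  # distribute functional + pseudo genes over clusters
  core <- sample(roster)
  sizes <- rep(length(core) %/% n_clusters, n_clusters)
  extra <- length(core) %% n_clusters
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  cluster_members <- split(core, rep(seq_len(n_clusters), times = sizes))

  # background contigs
  L <- spec$contig_length_bp
  gc2 <- spec$gc_content / 2
  at2 <- (1 - spec$gc_content) / 2
  contig_chars <- lapply(seq_len(spec$n_contigs), function(i)
    sample(c("A", "C", "G", "T"), L, replace = TRUE,
           prob = c(at2, gc2, gc2, at2)))
  names(contig_chars) <- sprintf("LG%d", seq_len(spec$n_contigs))

  truth <- list()
  gene_seqs <- list()
  plant <- function(contig_idx, start, gene, strand, guard) {
    cds <- gene$cds
    len <- nchar(cds)
    if (start < 0 || start + len > L)
      stop("sizing error: planned genes exceed contig capacity")
    fwd <- if (strand == "+") cds else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    contig_chars[[contig_idx]][seq(start + 1, start + len)] <<-
      strsplit(fwd, "")[[1]]
    if (guard) {
      gpos <- if (strand == "+") start - 3 else start + len
      if (gpos >= 0 && gpos + 3 <= L) {
        gseq <- if (strand == "+") c("T", "A", "A") else c("T", "T", "A")
        contig_chars[[contig_idx]][seq(gpos + 1, gpos + 3)] <<- gseq
      }
    }
    na_chr <- function(x) {
      if (is.null(x) || length(x) == 0 || is.na(x)) NA_character_
      else as.character(x)
    }
    truth[[length(truth) + 1]] <<- data.frame(
      gene_id = gene$gene_id, contig = names(contig_chars)[contig_idx],
      start = start, end = start + len, strand = strand,
      status = gene$status,
      group_label = na_chr(gene$group),
      subfamily_id = na_chr(gene$subfamily),
      mode = na_chr(gene$mode),
      missing = na_chr(gene$missing),
      disruptions = format_disruptions(gene$disruptions),
      stringsAsFactors = FALSE)
    gene_seqs[[gene$gene_id]] <<- cds
    start + len
  }

  margin <- 2000L
  for (ci in seq_len(spec$n_contigs)) {
    rows <- which(layout$contig == ci)
    cursor <- 0L
    for (ri in seq_along(rows)) {
      row_idx <- rows[ri]
      row <- layout[row_idx, ]
      members <- cluster_members[[row_idx]]
      tg <- Filter(function(t) t$cluster == row_idx, trunc_genes)
      body_len <- sum(vapply(members, function(g) nchar(g$cds),
                             numeric(1))) +
        spec$cluster_gap_bp * max(0, length(members) - 1)
      right_aligned <- ri == length(rows) && row$edge == "right" &&
        length(rows) == 1
      if (ri == 1) {
        cursor <- if (row$edge == "left" && length(tg) > 0) 0L else margin
        if (right_aligned)
          cursor <- max(cursor,
                        L - as.integer(body_len) - 600000L)
      } else {
        cursor <- cursor + spec$intercluster_gap_bp
      }
      if (row$edge == "left" && length(tg) > 0) {
        cursor <- plant(ci, 0L, tg[[1]], row$strand, guard = FALSE)
        cursor <- cursor + spec$cluster_gap_bp
      }
      for (g in members) {
        cursor <- plant(ci, as.integer(cursor), g, row$strand,
                        guard = TRUE)
        cursor <- cursor + spec$cluster_gap_bp
      }
      cursor <- cursor - spec$cluster_gap_bp
      if (row$edge == "right" && length(tg) > 0) {
        flen <- nchar(tg[[1]]$cds)
        if (L - flen - cursor > 1e6)
          stop("sizing error: right-edge truncated gene too far from ",
               "its cluster")
        cursor <- plant(ci, as.integer(L - flen), tg[[1]], row$strand,
                        guard = FALSE)
      }
    }
    # decoys: far from any cluster, inside the intercluster gap or the
    # empty arm of single-cluster contigs
    dec_idx <- which(seq_len(spec$n_decoys) %% spec$n_contigs ==
                       (ci %% spec$n_contigs))
    if (length(dec_idx) > 0) {
      anchors <- seq(0.25, 0.75, length.out = length(dec_idx))
      occupied <- do.call(rbind, lapply(truth, function(t)
        if (t$contig == names(contig_chars)[ci]) c(t$start, t$end)))
      for (di in seq_along(dec_idx)) {
        g <- decoys[[dec_idx[di]]]
        pos <- as.integer(anchors[di] * L)
        glen <- nchar(g$cds)
        ok <- function(p) is.null(occupied) ||
          all(p + glen + 20000 < occupied[, 1] |
                p - 20000 > occupied[, 2])
        while (!ok(pos)) pos <- pos + 50000L
        plant(ci, pos, g, if (di %% 2 == 0) "+" else "-", guard = TRUE)
      }
    }
  }

  truth_df <- do.call(rbind, truth)
  truth_df <- truth_df[order(truth_df$contig, truth_df$start), ,
                       drop = FALSE]
  rownames(truth_df) <- NULL

  contigs <- Biostrings::DNAStringSet(vapply(contig_chars, paste,
                                             character(1), collapse = ""))

  # panels: one query per group (the founders), three labeled references
  # per group (plus theta, a non-OR type II control), three decoy
  # founders plus variants
  set.seed(spec$seed + 17)
  ref_groups <- unique(c(groups_used, "theta"))
  queries <- setNames(
    lapply(groups_used, function(g) protein_string(group_founder(g))),
    paste0("query_", groups_used))
  refs <- list(); ref_labels <- character(0)
  for (g in ref_groups) {
    for (r in 1:3) {
      nm <- sprintf("ref_%s_%d", g, r)
      refs[[nm]] <- protein_string(mutate_protein(group_founder(g), 0.12))
      ref_labels <- c(ref_labels, setNames(g, nm))
    }
  }
  decoy_panel <- setNames(
    lapply(seq_along(dec_founders), function(i)
      protein_string(dec_founders[[i]])),
    sprintf("decoy_ref_%d", seq_along(dec_founders)))

  list(contigs = contigs, truth = truth_df, gene_seqs = gene_seqs,
       panels = list(
         queries = unlist(queries),
         references = reference_panel(unlist(refs), ref_labels,
                                      unlist(decoy_panel))),
       n_clusters_planned = n_clusters, spec = spec)
}

format_disruptions <- function(disruptions) {
  if (length(disruptions) == 0) return(NA_character_)
  paste(vapply(disruptions, function(d)
    sprintf("%s:%d", d$kind, d$codon_index), character(1)),
    collapse = ";")
}

parse_disruptions <- function(x) {
  if (is.na(x) || !nzchar(x)) return(list())
  lapply(strsplit(x, ";", fixed = TRUE)[[1]], function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    list(kind = parts[1], codon_index = as.integer(parts[2]))
  })
}

#' Write a simulated genome to disk
#'
#' Contigs as FASTA, truth as BED6 plus a TSV with status/group/subfamily
#' columns, panels as FASTA, and the generator parameters as a key-value
#' config file.
#'
#' @param sim output of [assemble_genome()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    contigs = file.path(dir, "contigs.fasta"),
    truth_bed = file.path(dir, "truth.bed"),
    truth_tsv = file.path(dir, "truth.tsv"),
    queries = file.path(dir, "queries.fasta"),
    references = file.path(dir, "references.fasta"),
    ref_labels = file.path(dir, "reference_groups.tsv"),
    decoys = file.path(dir, "decoys.fasta"),
    spec = file.path(dir, "generator.cfg"))
  write_fasta(sim$contigs, paths[["contigs"]])
  tr <- sim$truth
  write_bed(data.frame(contig = tr$contig, start = tr$start, end = tr$end,
                       name = tr$gene_id, score = 0, strand = tr$strand),
            paths[["truth_bed"]])
  write_tsv_report(tr, paths[["truth_tsv"]])
  write_fasta(sim$panels$queries, paths[["queries"]])
  write_fasta(sim$panels$references$or, paths[["references"]])
  write_tsv_report(
    data.frame(ref_id = names(sim$panels$references$or_groups),
               group_label = unname(sim$panels$references$or_groups)),
    paths[["ref_labels"]])
  write_fasta(sim$panels$references$decoy, paths[["decoys"]])
  sp <- sim$spec
  keys <- setdiff(names(unclass(sp)), "subfamily_plan")
  writeLines(c(
    vapply(keys, function(k) sprintf("%s = %s", k,
                                     format(sp[[k]], scientific = FALSE)),
           character(1)),
    sprintf("subfamily_plan = %s",
            paste(sprintf("%s:%s:%d:%g", sp$subfamily_plan$subfamily,
                          sp$subfamily_plan$group,
                          sp$subfamily_plan$n_members,
                          sp$subfamily_plan$identity_target),
                  collapse = ","))),
    paths[["spec"]])
  invisible(paths)
}

#' Compare recovered models with the planted truth
#'
#' Matches every non-decoy truth gene to a recovered model on the same
#' contig and strand with interval overlap of at least `min_overlap` of
#' the truth interval, and checks the recovered status. Models whose best
#' overlap is a planted decoy count as decoy leakage.
#'
#' @param models classified models (with `status`).
#' @param truth truth table from [assemble_genome()].
#' @param min_overlap minimum truth-interval overlap fraction.
#' @return list: `per_gene` (truth rows with `recovered`,
#'   `status_correct`, `exact_interval`), `recovery_pct`,
#'   `status_correct_pct`, `decoy_leakage`, `n_models`.
#' @export
evaluate_recovery <- function(models, truth, min_overlap = 0.8) {
  genes <- truth[truth$status != "decoy", , drop = FALSE]
  per <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cand <- models[models$contig == g$contig & models$strand == g$strand, ,
                   drop = FALSE]
    ov <- pmax(0, pmin(cand$end, g$end) - pmax(cand$start, g$start))
    hit <- which(ov >= min_overlap * (g$end - g$start))
    if (length(hit) == 0) {
      data.frame(gene_id = g$gene_id, truth_status = g$status,
                 recovered = FALSE, model_id = NA_character_,
                 model_status = NA_character_, status_correct = FALSE,
                 exact_interval = FALSE, stringsAsFactors = FALSE)
    } else {
      best <- hit[which.max(ov[hit])]
      data.frame(gene_id = g$gene_id, truth_status = g$status,
                 recovered = TRUE, model_id = cand$gene_id[best],
                 model_status = cand$status[best],
                 status_correct = identical(cand$status[best], g$status),
                 exact_interval = cand$start[best] == g$start &&
                   cand$end[best] == g$end,
                 stringsAsFactors = FALSE)
    }
  })
  per <- do.call(rbind, per)
  dec <- truth[truth$status == "decoy", , drop = FALSE]
  leak <- 0L
  if (nrow(dec) > 0 && nrow(models) > 0) {
    for (i in seq_len(nrow(dec))) {
      d <- dec[i, ]
      cand <- models[models$contig == d$contig, , drop = FALSE]
      ov <- pmax(0, pmin(cand$end, d$end) - pmax(cand$start, d$start))
      if (any(ov > 0.5 * (d$end - d$start))) leak <- leak + 1L
    }
  }
  list(per_gene = per,
       recovery_pct = 100 * mean(per$recovered),
       status_correct_pct = 100 * mean(per$status_correct),
       decoy_leakage = leak, n_models = nrow(models))
}
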