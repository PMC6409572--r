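# End-to-end pipeline: search -> rescue -> filter/classify -> organize ->
# group assignment -> subfamilies -> dN/dS -> motifs.

#' Run the OR mining pipeline on a genome
#'
#' Executes every stage of the identification protocol: translated search
#' with the configured e-value cutoff, best-hit locus selection, ORF
#' rescue in the configured flank, reciprocal filtering against non-OR
#' GPCR decoys, three-way classification, megabase cluster detection and
#' per-chromosome summaries, NJ group assignment, subfamily clustering of
#' functional genes, per-group NG86 dN/dS, and motif/sequon scanning.
#'
#' @param contigs named [Biostrings::DNAStringSet].
#' @param queries named query protein panel.
#' @param references a [reference_panel()] (labeled ORs + decoys).
#' @param config a [pipeline_config()].
#' @param motif_set motif definitions (default [default_motif_set()]).
#' @param species species label used in subfamily output.
#' @param prefilter seed-prefilter switch passed to [search_genome()].
#' @return list with `hits`, `loci`, `models`, `clusters`,
#'   `chromosome_summary`, `orientation`, `assignments`, `group_table`,
#'   `subfamilies`, `dnds`, `motif_presence`, `motif_patterns`,
#'   `sequons`.
#' @export
run_or_pipeline <- function(contigs, queries, references,
                            config = pipeline_config(),
                            motif_set = default_motif_set(),
                            species = "this_study", prefilter = TRUE) {
  hits <- search_genome(queries, contigs, evalue_max = config$evalue_max,
                        prefilter = prefilter)
  or_log("search", nrow(hits), " hits at e <= ", config$evalue_max)
  loci <- select_best_hits(hits, chain_gap_bp = config$chain_gap_bp)
  or_log("search", nrow(loci), " candidate loci")
  models <- build_gene_models(loci, contigs, flank_bp = config$flank_bp)
  or_log("rescue", nrow(models), " rescued models")
  models <- classify_models(models, references, config)
  or_log("classify", nrow(models), " classified OR models (",
         sum(models$status == "functional"), " functional, ",
         sum(models$status == "pseudogene"), " pseudogene, ",
         sum(models$status == "truncated"), " truncated)")

  clusters <- detect_clusters(models, gap_bp = config$cluster_gap_bp)
  chrom <- summarize_by_chromosome(models, clusters)
  orient <- orientation_stats(clusters, models)

  proteins <- setNames(models$protein, models$gene_id)
  assignments <- assign_groups(proteins, references,
                               bootstrap_reps = config$bootstrap_reps,
                               seed = config$seed)
  models$group_label <- assignments$group_label[
    match(models$gene_id, assignments$gene_id)]
  statuses <- setNames(models$status, models$gene_id)
  group_table <- group_count_table(assignments, statuses,
                                   species = species)

  fun <- models[models$status == "functional", , drop = FALSE]
  subfamilies <- NULL
  if (nrow(fun) >= 2) {
    subfamilies <- cluster_subfamilies(
      data.frame(gene_id = fun$gene_id, species = species,
                 protein = fun$protein, stringsAsFactors = FALSE),
      subfamily_cutoff = config$subfamily_identity_pct,
      family_cutoff = config$family_identity_pct)
    models$subfamily_id <- subfamilies$subfamily_id[
      match(models$gene_id, subfamilies$gene_id)]
  } else {
    models$subfamily_id <- NA_character_
  }

  dnds <- NULL
  if (nrow(fun) >= 2) {
    cds_set <- setNames(lapply(seq_len(nrow(fun)), function(i)
      model_cds(fun[i, ], contigs)), fun$gene_id)
    grp <- setNames(assignments$group_label[
      match(fun$gene_id, assignments$gene_id)], fun$gene_id)
    dnds <- group_average_dnds(cds_set,
                               setNames(fun$protein, fun$gene_id), grp)
  }

  presence <- t(vapply(fun$protein, function(p)
    scan_motifs(p, motif_set)$present,
    logical(length(motif_set))))
  rownames(presence) <- fun$gene_id
  motif_patterns <- if (nrow(presence) > 0)
    motif_pattern_frequencies(presence) else NULL
  sequons <- lapply(setNames(fun$protein, fun$gene_id), find_sequons)

  list(hits = hits, loci = loci, models = models, clusters = clusters,
       chromosome_summary = chrom, orientation = orient,
       assignments = assignments, group_table = group_table,
       subfamilies = subfamilies, dnds = dnds,
       motif_presence = presence, motif_patterns = motif_patterns,
       sequons = sequons)
}

# Strand-space coding sequence of a model, trailing stop included.
model_cds <- function(model, contigs) {
  ss <- strand_space(contigs[[model$contig]], model$strand)
  iv <- ss_from_forward(ss, model$start, model$end)
  substr(ss$seq, iv[1] + 1, iv[2])
}

#' Write the pipeline's report files
#'
#' Emits every stage's table under `dir`: hits (outfmt-6 style), gene
#' models (GFF3 + protein FASTA), classification report, clusters (BED),
#' chromosome summary, group assignments and counts, subfamilies, dN/dS,
#' motif patterns, and sequon counts.
#'
#' @param result output of [run_or_pipeline()].
#' @param dir output directory.
#' @param contigs the searched contigs (for GFF validation).
#' @return named vector of written paths, invisibly.
#' @export
write_pipeline_reports <- function(result, dir, contigs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  p <- function(name) file.path(dir, name)
  write_tsv_report(hits_outfmt6(result$hits), p("hits.tsv"))
  paths["hits"] <- p("hits.tsv")
  m <- result$models
  lengths <- if (is.null(contigs)) NULL else
    setNames(Biostrings::width(contigs), names(contigs))
  write_gene_models_gff(m, p("models.gff3"), contig_lengths = lengths)
  paths["models_gff"] <- p("models.gff3")
  write_fasta(setNames(m$protein, m$gene_id), p("proteins.fasta"))
  paths["proteins"] <- p("proteins.fasta")
  write_tsv_report(classification_report(m), p("classification.tsv"))
  paths["classification"] <- p("classification.tsv")
  cl <- result$clusters
  write_bed(data.frame(contig = cl$contig, start = cl$start,
                       end = cl$end, name = cl$cluster_id,
                       score = cl$n_members, strand = "."),
            p("clusters.bed"))
  paths["clusters"] <- p("clusters.bed")
  write_tsv_report(result$chromosome_summary, p("chromosome_summary.tsv"))
  paths["chromosome_summary"] <- p("chromosome_summary.tsv")
  write_tsv_report(result$assignments, p("group_assignments.tsv"))
  paths["assignments"] <- p("group_assignments.tsv")
  write_tsv_report(result$group_table, p("group_counts.tsv"))
  paths["group_counts"] <- p("group_counts.tsv")
  if (!is.null(result$subfamilies)) {
    write_tsv_report(result$subfamilies, p("subfamilies.tsv"))
    paths["subfamilies"] <- p("subfamilies.tsv")
  }
  if (!is.null(result$dnds) && !is.null(result$dnds$groups)) {
    write_tsv_report(result$dnds$groups, p("dnds_groups.tsv"),
                     comment = paste("NG86 counting method with",
                                     "Jukes-Cantor correction"))
    paths["dnds"] <- p("dnds_groups.tsv")
  }
  if (!is.null(result$motif_patterns)) {
    write_tsv_report(result$motif_patterns, p("motif_patterns.tsv"))
    paths["motif_patterns"] <- p("motif_patterns.tsv")
  }
  seq_df <- data.frame(gene_id = names(result$sequons),
                       n_sequons = vapply(result$sequons, length,
                                          integer(1)),
                       stringsAsFactors = FALSE)
  write_tsv_report(seq_df, p("sequons.tsv"))
  paths["sequons"] <- p("sequons.tsv")
  invisible(paths)
}
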