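#' Run the full pipeline end-to-end on simulated data
#'
#' Simulates a met-1-like sample (MES-4 maintenance marking only), a
#' wild-type-like sample (transcription-coupled marking over all expressed
#' classes), a pan-H3 control and an input control, each in replicate;
#' builds normalized replicate-averaged coverage; computes gene-body
#' scores, the met-1-like vs wild-type-like scatter table, X:autosome
#' summaries, TSS/TES metagene profiles for germline-specific and
#' soma-expressed genes; and derives expression-class gene sets from
#' simulated tag tables. All outputs are written as plain text under
#' `outdir` together with a YAML configuration echo and a summary report;
#' identical seeds give identical reports.
#'
#' @param outdir output directory (created if needed)
#' @param seed integer seed driving every random draw
#' @param n_reads reads per replicate (default 2e5)
#' @param replicates replicates per sample (default 2)
#' @param n_autosomes,chrom_length,genes_per_chrom genome/annotation scale
#' @return invisibly, a list with the tracks, score tables, scatter,
#'   profiles, gene sets and the summary lines
#' @export
run_demo <- function(outdir, seed = 1L, n_reads = 2e5, replicates = 2L,
                     n_autosomes = 5L, chrom_length = 1e5,
                     genes_per_chrom = 30L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("demo stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genome <- stage("genome", toy_genome(n_autosomes, chrom_length, TRUE))
  ann <- stage("annotation",
               annotate_genes(genome, genes_per_chrom, seed = seed))
  tags <- stage("tags", simulate_expression_tags(ann, seed = seed + 1L))

  models <- list(met1_like = enrichment_model("mes4_maintenance"),
                 wildtype_like = enrichment_model("transcription_coupled"),
                 pan_h3 = enrichment_model("pan_h3"),
                 input = enrichment_model("input"))
  tracks <- stage("coverage", lapply(names(models), function(s) {
    reps <- lapply(seq_len(replicates), function(r)
      simulate_reads(genome, ann, models[[s]], n_reads, seed = seed,
                     replicate = r + 10L * match(s, names(models)),
                     sample_id = s))
    build_coverage(reps, genome, sample_id = s)
  }))
  names(tracks) <- names(models)

  scores <- stage("scores",
                  lapply(tracks, gene_body_score, genes = ann))
  germline_ids <- ann$gene_id[ann$class == "germline"]
  soma_ids <- ann$gene_id[ann$class == "soma"]
  sc <- stage("scatter", scatter_table(scores$met1_like,
                                       scores$wildtype_like,
                                       highlight = germline_ids))
  sums <- lapply(tracks, chromosome_summary)

  profs <- stage("metagene", list(
    tss_germline = metagene_profile(tracks$met1_like, ann, germline_ids,
                                    "tss"),
    tss_soma = metagene_profile(tracks$met1_like, ann, soma_ids, "tss"),
    tes_germline = metagene_profile(tracks$met1_like, ann, germline_ids,
                                    "tes")))

  sets <- stage("genesets", list(
    ubiquitous = define_ubiquitous(tags),
    somatic = define_somatic(tags),
    germline_enriched = define_germline_enriched(germline_ids),
    larval_adult_germline_specific = define_larval_adult_germline_specific(
      germline_ids, sage_germline_expressed(tags), germline_ids)))

  auc <- rank_auc(scores$met1_like$log10_score[
                    scores$met1_like$gene_id %in% germline_ids],
                  scores$met1_like$log10_score[
                    scores$met1_like$gene_id %in% soma_ids])
  p <- profs$tss_germline
  body5 <- mean(p$mean[p$offset >= 0 & p$offset < 500])
  body3 <- mean(p$mean[p$offset >= 1000 & p$offset < 1500])

  summary_lines <- c(
    sprintf("seed: %d  reads_per_replicate: %d  replicates: %d", seed,
            as.integer(n_reads), replicates),
    sprintf("x_autosome_ratio met1_like: %.4f (expected < 1)",
            sums$met1_like$x_autosome_ratio),
    sprintf("x_autosome_ratio pan_h3: %.4f (expected ~ 1)",
            sums$pan_h3$x_autosome_ratio),
    sprintf("x_autosome_ratio input: %.4f (expected ~ 1)",
            sums$input$x_autosome_ratio),
    sprintf("auc germline vs soma (met1_like): %.4f (expected >= 0.95)",
            auc),
    sprintf("tss profile mean (0,500] vs (1000,1500]: %.4f vs %.4f (5' bias expected)",
            body5, body3),
    sprintf("scatter genes plotted: %d (dropped undefined: %d)", nrow(sc),
            attr(sc, "dropped")),
    sprintf("gene sets: ubiquitous %d, somatic %d, germline-specific %d",
            length(sets$ubiquitous), length(sets$somatic),
            length(sets$larval_adult_germline_specific)))

  # --- outputs -------------------------------------------------------
  write_gene_annotation(ann, file.path(outdir, "genes.bed"),
                        file.path(outdir, "gene_classes.tsv"))
  write_tag_table(tags, file.path(outdir, "expression_tags.tsv"))
  for (s in names(tracks))
    write_bedgraph(tracks[[s]], file.path(outdir, paste0(s, ".bedgraph")))
  for (s in names(scores))
    utils::write.table(scores[[s]],
                       file.path(outdir, paste0("scores_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sc, file.path(outdir, "scatter_met1_vs_wildtype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(profs))
    utils::write.table(profs[[s]],
                       file.path(outdir, paste0("profile_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(sets))
    writeLines(sets[[s]], file.path(outdir, paste0("set_", s, ".txt")))
  yaml::write_yaml(list(
    seed = as.integer(seed), n_reads = as.integer(n_reads),
    replicates = as.integer(replicates),
    extension_bp = 200, bin_bp = 50,
    tss_window = c(upstream = 1000, downstream = 1500),
    tes_window = c(upstream = 1500, downstream = 1000),
    genome = list(n_autosomes = as.integer(n_autosomes),
                  chrom_length = chrom_length, include_X = TRUE),
    models = lapply(models, function(m) m[c("mode", "background_fraction",
                                            "positional_bias",
                                            "bias_strength",
                                            "x_weight_multiplier")])),
    file.path(outdir, "config.yaml"))
  writeLines(summary_lines, file.path(outdir, "report.txt"))

  invisible(list(genome = genome, annotation = ann, tags = tags,
                 tracks = tracks, scores = scores, scatter = sc,
                 chromosome_summaries = sums, profiles = profs,
                 gene_sets = sets, auc = auc, summary = summary_lines))
}
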