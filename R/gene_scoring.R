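#' Per-gene gene-body enrichment scores
#'
#' Averages per-base-pair signal over each gene body — every base between
#' the transcription start and end sites, introns included, regardless of
#' strand — and reports the log10 of that mean. Zero-mean genes get an
#' undefined (NA) log10 score and are excluded from downstream scatter
#' tables unless a pseudocount is supplied.
#'
#' @param track a `coverage_track`
#' @param genes a `gene_annotation`
#' @param pseudocount added to the mean before log10 (default 0: no data
#'   invented; zero scores stay undefined)
#' @return a `gene_score_table`: data.frame with `gene_id`, `class`,
#'   `chrom`, `start`, `end`, `length`, `mean_signal`, `log10_score`
#' @export
gene_body_score <- function(track, genes, pseudocount = 0) {
  stopifnot(inherits(track, "coverage_track"))
  if (!inherits(genes, "gene_annotation")) genes <- gene_annotation(genes)
  if (any(genes$end <= genes$start)) stop("zero-length gene body")
  lens <- .chrom_length(track$genome, genes$chrom)
  if (any(genes$start < 0 | genes$end > lens))
    stop("gene outside chromosome bounds")
  csums <- lapply(track$values, function(v) c(0, cumsum(v)))
  mean_signal <- vapply(seq_len(nrow(genes)), function(i) {
    cs <- csums[[genes$chrom[i]]]
    (cs[genes$end[i] + 1] - cs[genes$start[i] + 1]) /
      (genes$end[i] - genes$start[i])
  }, 0)
  m <- mean_signal + pseudocount
  log10_score <- ifelse(m > 0, log10(m), NA_real_)
  out <- data.frame(gene_id = genes$gene_id, class = genes$class,
                    chrom = genes$chrom, start = genes$start,
                    end = genes$end, length = genes$end - genes$start,
                    mean_signal = mean_signal, log10_score = log10_score,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- track$sample_id
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Paired log10 score table for sample-vs-sample scatter plots
#'
#' Joins two score tables on their common gene universe and reports per
#' gene the two log10 scores and a highlight flag. Genes with an undefined
#' log10 score on either axis are excluded and counted in the drop report
#' (attribute `dropped`).
#'
#' @param scores_a,scores_b `gene_score_table`s (e.g. met-1-like vs
#'   wild-type-like samples)
#' @param highlight character vector of gene ids to flag
#' @return data.frame with `gene_id`, `class`, `log10_a`, `log10_b`,
#'   `highlighted`; attributes `dropped` (count) and `samples`
#' @export
scatter_table <- function(scores_a, scores_b, highlight = character()) {
  common <- intersect(scores_a$gene_id, scores_b$gene_id)
  if (length(common) == 0L) stop("score tables share no genes")
  a <- scores_a[match(common, scores_a$gene_id), ]
  b <- scores_b[match(common, scores_b$gene_id), ]
  ok <- !is.na(a$log10_score) & !is.na(b$log10_score)
  out <- data.frame(gene_id = common[ok], class = a$class[ok],
                    log10_a = a$log10_score[ok], log10_b = b$log10_score[ok],
                    highlighted = common[ok] %in% highlight,
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- sum(!ok)
  attr(out, "samples") <- c(a = attr(scores_a, "sample_id") %||% "a",
                            b = attr(scores_b, "sample_id") %||% "b")
  out
}

#' Per-chromosome mean signal and X:autosome ratio
#'
#' Mean signal per chromosome plus the ratio of the X mean to the pooled
#' autosomal mean (total autosomal signal over total autosomal length).
#' Without an X chromosome the ratio is NA.
#'
#' @param track a `coverage_track`
#' @param genome a `genome_model` (default: the track's)
#' @return list with `per_chrom` (data.frame chrom, length, mean_signal,
#'   is_X) and `x_autosome_ratio`
#' @export
chromosome_summary <- function(track, genome = track$genome) {
  .check_genome(genome)
  tot <- vapply(track$values[genome$chrom], sum, 0)
  per <- data.frame(chrom = genome$chrom, length = genome$length,
                    mean_signal = tot / genome$length, is_X = genome$is_X,
                    stringsAsFactors = FALSE)
  ratio <- if (any(genome$is_X)) {
    auto <- !genome$is_X
    (sum(tot[genome$is_X]) / sum(genome$length[genome$is_X])) /
      (sum(tot[auto]) / sum(genome$length[auto]))
  } else NA_real_
  list(per_chrom = per, x_autosome_ratio = ratio)
}

#' Call enriched genes against an intergenic background quantile
#'
#' Genes whose gene-body mean exceeds the given quantile of per-base-pair
#' signal over intergenic bases (bases outside every gene body) are
#' called enriched. This is an explicit reconstruction of "clear
#' enrichment" as a background-quantile exceedance; the threshold is
#' echoed in the result.
#'
#' @param scores a `gene_score_table` (carries the gene coordinates)
#' @param track the `coverage_track` the scores came from
#' @param background_quantile probability in (0, 1), default 0.95
#' @return list with `enriched` (gene ids), `threshold`,
#'   `background_quantile`, `n_intergenic_bases`
#' @export
classify_enriched <- function(scores, track, background_quantile = 0.95) {
  if (background_quantile <= 0 || background_quantile >= 1)
    stop("`background_quantile` must be in (0, 1)")
  g <- track$genome
  inter <- unlist(lapply(g$chrom, function(cn) {
    v <- track$values[[cn]]
    genic <- logical(length(v))
    sel <- scores$chrom == cn
    for (i in which(sel))
      genic[(scores$start[i] + 1):scores$end[i]] <- TRUE
    v[!genic]
  }), use.names = FALSE)
  if (length(inter) == 0L) stop("no intergenic bases: cannot form background")
  thr <- stats::quantile(inter, background_quantile, names = FALSE)
  list(enriched = scores$gene_id[scores$mean_signal > thr],
       threshold = thr, background_quantile = background_quantile,
       n_intergenic_bases = length(inter))
}

#' Rank-based AUC separating two score groups
#'
#' Probability that a randomly chosen positive-group score exceeds a
#' randomly chosen negative-group score (ties count half): the
#' Wilcoxon/Mann-Whitney statistic scaled to [0, 1]. Used to quantify how
#' well gene-body scores separate expression classes.
#'
#' @param positive,negative numeric score vectors (NAs dropped)
#' @return AUC in [0, 1]
#' @export
rank_auc <- function(positive, negative) {
  positive <- positive[!is.na(positive)]
  negative <- negative[!is.na(negative)]
  if (!length(positive) || !length(negative))
    stop("both groups must be non-empty")
  r <- rank(c(positive, negative))
  np <- length(positive)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(negative))
}
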