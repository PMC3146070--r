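#' Enrichment model for read simulation
#'
#' Describes where simulated ChIP fragments come from. A fraction
#' `background_fraction` of reads is uniform over the genome; the rest are
#' drawn from gene bodies, with genes sampled proportionally to
#' `class_weights[class] * gene length * (x_weight_multiplier if X-linked)`
#' and a within-gene position drawn with a linear 5' or 3' bias.
#'
#' Preset modes encode the biology the simulator emulates:
#' \describe{
#'   \item{mes4_maintenance}{MES-4-maintained marking: germline and
#'     ubiquitous gene bodies, soma excluded, mild 5' bias, X depleted
#'     (multiplier 0.1). Emulates H3K36me3 in a met-1 mutant, where only
#'     the transcription-independent MES-4 signal remains.}
#'   \item{transcription_coupled}{Cotranscriptional marking: all expressed
#'     classes, 3' bias, no X depletion. Emulates the MET-1 contribution
#'     in wild type.}
#'   \item{pan_h3}{Pan-histone H3 control: uniform over the genome.}
#'   \item{input}{Input chromatin: uniform over the genome.}
#' }
#'
#' @param mode one of "mes4_maintenance", "transcription_coupled",
#'   "pan_h3", "input"
#' @param background_fraction probability in [0,1] that a read is uniform
#'   background rather than gene-body derived
#' @param positional_bias "five_prime", "three_prime" or "uniform"
#' @param bias_strength slope of the linear within-gene position density,
#'   in [0, 1]; 0 is uniform
#' @param class_weights named nonnegative weights per expression class
#' @param x_weight_multiplier multiplier applied to X-linked gene weights
#' @return an `enrichment_model` list
#' @export
enrichment_model <- function(mode = c("mes4_maintenance",
                                      "transcription_coupled",
                                      "pan_h3", "input"),
                             background_fraction = NULL,
                             positional_bias = NULL,
                             bias_strength = NULL,
                             class_weights = NULL,
                             x_weight_multiplier = NULL) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    mes4_maintenance = list(background_fraction = 0.2,
                            positional_bias = "five_prime",
                            bias_strength = 0.6,
                            class_weights = c(germline = 1, ubiquitous = 1,
                                              soma = 0),
                            x_weight_multiplier = 0.1),
    transcription_coupled = list(background_fraction = 0.2,
                                 positional_bias = "three_prime",
                                 bias_strength = 0.6,
                                 class_weights = c(germline = 1,
                                                   ubiquitous = 1, soma = 1),
                                 x_weight_multiplier = 1),
    pan_h3 = list(background_fraction = 1, positional_bias = "uniform",
                  bias_strength = 0, class_weights = numeric(0),
                  x_weight_multiplier = 1),
    input = list(background_fraction = 1, positional_bias = "uniform",
                 bias_strength = 0, class_weights = numeric(0),
                 x_weight_multiplier = 1))
  m <- defaults
  for (f in names(defaults)) {
    v <- get(f)
    if (!is.null(v)) m[[f]] <- v
  }
  m$mode <- mode
  m$positional_bias <- match.arg(m$positional_bias,
                                 c("five_prime", "three_prime", "uniform"))
  if (m$background_fraction < 0 || m$background_fraction > 1)
    stop("`background_fraction` must be in [0, 1]")
  if (m$bias_strength < 0 || m$bias_strength > 1)
    stop("`bias_strength` must be in [0, 1] (linear density stays >= 0)")
  if (any(!is.finite(m$class_weights)) || any(m$class_weights < 0))
    stop("class weights must be finite and >= 0")
  if (m$x_weight_multiplier < 0 || !is.finite(m$x_weight_multiplier))
    stop("`x_weight_multiplier` must be finite and >= 0")
  if (!mode %in% c("pan_h3", "input") && m$background_fraction < 1 &&
      (length(m$class_weights) == 0L || all(m$class_weights == 0)))
    stop("at least one nonzero class weight is required in mode ", mode)
  structure(m, class = "enrichment_model")
}

#' @export
print.enrichment_model <- function(x, ...) {
  cat(sprintf("enrichment model '%s': background %.2f, bias %s (%.2f), x-mult %.2f\n",
              x$mode, x$background_fraction, x$positional_bias,
              x$bias_strength, x$x_weight_multiplier))
  if (length(x$class_weights))
    cat("  class weights:",
        paste(sprintf("%s=%g", names(x$class_weights), x$class_weights),
              collapse = ", "), "\n")
  invisible(x)
}

#' Simulate mapped single-end reads under an enrichment model
#'
#' Every read is either uniform background or drawn from a sampled source
#' gene (the truth label, kept in the read name) with the model's
#' within-gene positional bias, oriented by gene strand. Reads are
#' `read_length` bp, on a random strand, clamped to chromosome ends, and
#' returned sorted by (chrom, start). Identical arguments give
#' byte-identical output; replicates draw from independent streams derived
#' from `(seed, replicate)`.
#'
#' @param genome a `genome_model`
#' @param annotation a `gene_annotation` (may be NULL for pure-background
#'   modes)
#' @param model an `enrichment_model`
#' @param n_reads number of reads to emit (exactly)
#' @param read_length read length in bp (default 36, the mapped read
#'   length the coverage stage assumes)
#' @param seed integer seed
#' @param replicate replicate index (>= 1); changes the stream, not the
#'   configuration
#' @param sample_id label carried on the output
#' @return a `read_set`: data.frame with columns `chrom`, `start`, `end`,
#'   `name` (source gene id or "bg"), `strand`, plus attributes
#'   `sample_id` and `replicate`
#' @export
simulate_reads <- function(genome, annotation, model, n_reads,
                           read_length = 36, seed = 1L, replicate = 1L,
                           sample_id = model$mode) {
  .check_genome(genome)
  if (!inherits(model, "enrichment_model")) stop("expected an `enrichment_model`")
  if (n_reads < 1) stop("`n_reads` must be >= 1")
  if (read_length < 1) stop("`read_length` must be >= 1")
  n_reads <- as.integer(n_reads)

  gene_frac <- 1 - model$background_fraction
  w <- NULL
  if (gene_frac > 0) {
    if (is.null(annotation)) stop("annotation required unless background_fraction = 1")
    cw <- model$class_weights[annotation$class]
    cw[is.na(cw)] <- 0
    w <- as.numeric(cw) * (annotation$end - annotation$start) *
      ifelse(genome$is_X[match(annotation$chrom, genome$chrom)],
             model$x_weight_multiplier, 1)
    if (all(w == 0))
      stop("all gene sampling weights are zero under this model/annotation")
  }

  # one stream per (seed, replicate); kept below 2^31
  rng <- .local_rng((as.integer(seed) * 10007L + as.integer(replicate)) %%
                      .Machine$integer.max)

  is_bg <- rng$runif(n_reads) < model$background_fraction
  n_bg <- sum(is_bg)
  chrom <- character(n_reads)
  pos <- numeric(n_reads)
  src <- rep("bg", n_reads)

  if (n_bg > 0) {
    # chromosome ~ number of valid start positions, then uniform start
    navail <- pmax(genome$length - read_length + 1, 1)
    ci <- rng$sample_int(nrow(genome), n_bg, prob = navail)
    chrom[is_bg] <- genome$chrom[ci]
    pos[is_bg] <- floor(rng$runif(n_bg, 0, navail[ci]))
  }
  n_gene <- n_reads - n_bg
  if (n_gene > 0) {
    gi <- rng$sample_int(nrow(annotation), n_gene, prob = w)
    glen <- annotation$end[gi] - annotation$start[gi]
    u <- .sample_biased_position(rng$runif(n_gene), model$positional_bias,
                                 model$bias_strength)
    k <- pmin(floor(u * glen), glen - 1)  # offset from the 5' end
    p <- ifelse(annotation$strand[gi] == "+",
                annotation$start[gi] + k, annotation$end[gi] - 1 - k)
    chrom[!is_bg] <- annotation$chrom[gi]
    pos[!is_bg] <- p
    src[!is_bg] <- annotation$gene_id[gi]
  }

  clen <- .chrom_length(genome, chrom)
  end <- pmin(pos + read_length, clen)
  strand <- c("+", "-")[1L + (rng$runif(n_reads) < 0.5)]
  reads <- data.frame(chrom = chrom, start = pos, end = end, name = src,
                      strand = strand, stringsAsFactors = FALSE)
  o <- order(match(reads$chrom, genome$chrom), reads$start, reads$end)
  reads <- reads[o, , drop = FALSE]
  rownames(reads) <- NULL
  read_set(reads, sample_id = sample_id, replicate = replicate)
}

# Inverse-CDF sampling of the relative 5'->3' position u in [0,1) under
# density 1 + s*(1-2u) (five_prime); three_prime mirrors it.
.sample_biased_position <- function(q, bias, s) {
  if (bias == "uniform" || s == 0) return(q)
  # F(u) = u + s*u*(1-u); solve s*u^2 - (1+s)*u + F = 0 for u in [0,1]
  u <- ((1 + s) - sqrt((1 + s)^2 - 4 * s * q)) / (2 * s)
  u <- pmin(pmax(u, 0), 1 - 1e-12)
  if (bias == "three_prime") u <- 1 - u
  u
}

#' Construct/validate a read set
#'
#' @param df data.frame with columns chrom, start, end and optionally
#'   name/strand (strand defaults to "+")
#' @param sample_id sample label
#' @param replicate replicate index
#' @param genome optional `genome_model` for bounds validation
#' @return a `read_set` data.frame
#' @export
read_set <- function(df, sample_id = "sample", replicate = 1L,
                     genome = NULL) {
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop("read set needs columns chrom, start, end")
  if (!"strand" %in% names(df)) df$strand <- rep("+", nrow(df))
  if (!"name" %in% names(df)) df$name <- rep(".", nrow(df))
  if (nrow(df) > 0) {
    if (any(df$start < 0)) stop("read with start < 0")
    if (any(df$end <= df$start)) stop("read with end <= start")
    if (!all(df$strand %in% c("+", "-"))) stop("read strand must be '+' or '-'")
    if (!is.null(genome)) {
      lens <- .chrom_length(genome, df$chrom)
      if (any(df$end > lens)) stop("read beyond chromosome end")
    }
  }
  df <- as.data.frame(df[, c("chrom", "start", "end", "name", "strand")],
                      stringsAsFactors = FALSE)
  attr(df, "sample_id") <- sample_id
  attr(df, "replicate") <- as.integer(replicate)
  class(df) <- c("read_set", "data.frame")
  df
}

#' Simulate per-tissue SAGE-style expression tag counts
#'
#' Draws nonnegative integer tag counts per gene and tissue from Poisson
#' distributions whose means are set by the gene's expression class:
#' germline-class genes express only in germline, soma-class genes in the
#' somatic tissues only, ubiquitous genes everywhere. Unknown classes get
#' zero counts everywhere.
#'
#' @param annotation a `gene_annotation`
#' @param tissues tissue names; must include germline, muscle, nerve, gut
#' @param depth mean tag count in an expressing tissue (default 10)
#' @param seed integer seed
#' @return a `tag_table`: data.frame, first column `gene`, one count column
#'   per tissue
#' @export
simulate_expression_tags <- function(annotation,
                                     tissues = c("germline", "muscle",
                                                 "nerve", "gut"),
                                     depth = 10, seed = 1L) {
  required <- c("germline", "muscle", "nerve", "gut")
  known <- c(required)
  if (!all(required %in% tissues))
    stop("tissues must include: ", paste(required, collapse = ", "))
  if (!all(tissues %in% known))
    stop("unknown tissue name: ",
         paste(setdiff(tissues, known), collapse = ", "))
  somatic <- setdiff(tissues, "germline")
  rng <- .local_rng(seed)
  counts <- sapply(tissues, function(t) {
    mu <- switch(t, germline = ifelse(annotation$class %in%
                                        c("germline", "ubiquitous"), depth, 0),
                 ifelse(annotation$class %in% c("soma", "ubiquitous"),
                        depth, 0))
    rng$rpois(nrow(annotation), mu)
  })
  counts <- matrix(counts, nrow = nrow(annotation),
                   dimnames = list(NULL, tissues))
  out <- data.frame(gene = annotation$gene_id, counts,
                    stringsAsFactors = FALSE, check.names = FALSE)
  tag_table(out)
}

#' Construct/validate an expression tag table
#' @param df data.frame: first column `gene`, remaining columns nonnegative
#'   integer tissue tag counts
#' @return a `tag_table` data.frame
#' @export
tag_table <- function(df) {
  if (names(df)[1] != "gene") stop("first column must be `gene`")
  if (anyDuplicated(df$gene)) stop("duplicate gene ids in tag table")
  cnt <- as.matrix(df[, -1, drop = FALSE])
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    stop("tag counts must be nonnegative integers")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("tag_table", "data.frame")
  df
}
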