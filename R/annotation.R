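#' Simulate a classed gene annotation over a toy genome
#'
#' Places `genes_per_chrom` non-overlapping genes on every chromosome and
#' labels each with an expression class. Placement partitions each
#' chromosome into equal slots and draws one gene per slot, so genes never
#' overlap and windows around them stay mostly disjoint. Strand is drawn
#' uniformly. Coordinates are 0-based half-open; a gene stores
#' `(start, end, strand)` and its TSS/TES are strand-aware accessors
#' (TSS = `start` on "+", `end - 1` on "-").
#'
#' Expression classes mirror the breadth categories used for germline
#' chromatin work: `"germline"` (germline-specific), `"soma"`
#' (soma-expressed, silent in germline), `"ubiquitous"` (expressed in
#' germline and all somatic tissues). The X chromosome can receive its own
#' class mixture (`x_class_proportions`) to emulate the depletion of
#' germline-expressed genes from the X.
#'
#' @param genome a `genome_model`
#' @param genes_per_chrom genes to place on each chromosome
#' @param gene_length_range length-2 numeric, min/max gene length in bp
#' @param class_proportions named numeric summing to 1; class labels are the
#'   names (default germline/soma/ubiquitous = 0.3/0.4/0.3)
#' @param x_class_proportions optional named numeric used for X-linked genes
#'   (default: germline depleted to 0.05, remainder renormalized)
#' @param seed integer seed; identical seeds give identical annotations
#' @return a `gene_annotation`: data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `class`
#' @export
annotate_genes <- function(genome, genes_per_chrom,
                           gene_length_range = c(1000, 3000),
                           class_proportions = c(germline = 0.3, soma = 0.4,
                                                 ubiquitous = 0.3),
                           x_class_proportions = NULL,
                           seed = 1L) {
  .check_genome(genome)
  if (genes_per_chrom < 1) stop("`genes_per_chrom` must be >= 1")
  if (length(gene_length_range) != 2L || diff(gene_length_range) < 0)
    stop("`gene_length_range` must be c(min, max) with min <= max")
  .check_proportions(class_proportions)
  if (is.null(x_class_proportions)) {
    x_class_proportions <- class_proportions
    if ("germline" %in% names(x_class_proportions) &&
        length(x_class_proportions) > 1L) {
      x_class_proportions["germline"] <- 0.05
      others <- setdiff(names(x_class_proportions), "germline")
      x_class_proportions[others] <- x_class_proportions[others] *
        0.95 / sum(x_class_proportions[others])
    }
  }
  .check_proportions(x_class_proportions)

  slot_needed <- gene_length_range[2]
  if (any(genome$length / genes_per_chrom < slot_needed))
    stop("gene length exceeds chromosome slot: reduce `genes_per_chrom` ",
         "or gene lengths")

  rng <- .local_rng(seed)
  rows <- lapply(seq_len(nrow(genome)), function(ci) {
    len <- genome$length[ci]
    slot <- floor(len / genes_per_chrom)
    props <- if (genome$is_X[ci]) x_class_proportions else class_proportions
    glen <- floor(rng$runif(genes_per_chrom, gene_length_range[1],
                            gene_length_range[2] + 1))
    # uniform start within the slot, gene guaranteed to fit
    off <- floor(rng$runif(genes_per_chrom, 0, slot - glen + 1))
    start <- (seq_len(genes_per_chrom) - 1L) * slot + off
    strand <- c("+", "-")[1L + (rng$runif(genes_per_chrom) < 0.5)]
    cls <- names(props)[rng$sample_int(length(props), genes_per_chrom,
                                       prob = props)]
    data.frame(
      gene_id = sprintf("%s_g%03d", genome$chrom[ci], seq_len(genes_per_chrom)),
      chrom = genome$chrom[ci], start = start, end = start + glen,
      strand = strand, class = cls, stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  gene_annotation(ann, genome)
}

#' Construct/validate a gene annotation
#'
#' @param df data.frame with columns gene_id, chrom, start, end, strand and
#'   optionally class (missing classes become "unassigned")
#' @param genome optional `genome_model` for bounds validation
#' @return a `gene_annotation` data.frame
#' @export
gene_annotation <- function(df, genome = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (!"class" %in% names(df)) df$class <- "unassigned"
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(df$end <= df$start)) stop("gene with end <= start")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(genome)) {
    lens <- .chrom_length(genome, df$chrom)
    if (any(df$start < 0 | df$end > lens))
      stop("gene outside chromosome bounds")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Strand-aware transcription start sites (0-based)
#' @param ann a `gene_annotation`
#' @return integer-valued vector named by gene id
#' @export
tss <- function(ann) {
  stats::setNames(ifelse(ann$strand == "+", ann$start, ann$end - 1),
                  ann$gene_id)
}

#' Strand-aware transcription end sites (0-based)
#' @param ann a `gene_annotation`
#' @return integer-valued vector named by gene id
#' @export
tes <- function(ann) {
  stats::setNames(ifelse(ann$strand == "+", ann$end - 1, ann$start),
                  ann$gene_id)
}

.check_proportions <- function(p) {
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop("class proportions must be a named vector")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("class proportions must be >= 0 and sum to 1")
  invisible(p)
}

# Private RNG stream: callers get reproducibility without touching the
# global .Random.seed.
.local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  with_state <- function(f) {
    function(...) {
      outer <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(outer)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", outer, envir = globalenv())
      })
      f(...)
    }
  }
  list(
    runif = with_state(stats::runif),
    rpois = with_state(stats::rpois),
    sample_int = with_state(function(n, size, prob = NULL)
      sample.int(n, size, replace = TRUE, prob = prob))
  )
}
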