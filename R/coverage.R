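#' Coverage track container
#'
#' Per-base-pair signal vectors, one per chromosome, with a normalization
#' state machine: `raw` (integer read pileup) -> `median_scaled` (scaled so
#' the genome-wide normalization median hits a target) ->
#' `replicate_averaged` (mean over scaled replicates). Scaling always
#' precedes averaging.
#'
#' @param values named list of numeric vectors, one per chromosome, each of
#'   the chromosome's length
#' @param genome a `genome_model`
#' @param sample_id sample label
#' @param normalization_state one of "raw", "median_scaled",
#'   "replicate_averaged"
#' @param scale_factor multiplicative factor applied so far (1 for raw)
#' @return a `coverage_track`
#' @export
coverage_track <- function(values, genome, sample_id = "sample",
                           normalization_state = "raw", scale_factor = 1) {
  .check_genome(genome)
  normalization_state <- match.arg(normalization_state,
                                   c("raw", "median_scaled",
                                     "replicate_averaged"))
  if (!setequal(names(values), genome$chrom))
    stop("track chromosomes must match the genome")
  values <- values[genome$chrom]
  if (!all(lengths(values) == genome$length))
    stop("track vector lengths must equal chromosome lengths")
  if (any(vapply(values, function(v) any(v < 0), TRUE)))
    stop("track values must be >= 0")
  structure(list(values = values, genome = genome, sample_id = sample_id,
                 normalization_state = normalization_state,
                 scale_factor = scale_factor),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage track '%s' [%s], %d chromosomes, scale %.4g\n",
              x$sample_id, x$normalization_state, length(x$values),
              x$scale_factor))
  tot <- vapply(x$values, sum, 0)
  print(data.frame(chrom = names(x$values),
                   length = vapply(x$values, length, 0L),
                   mean_signal = signif(tot / lengths(x$values), 4)),
        row.names = FALSE)
  invisible(x)
}

#' Extend mapped reads to the expected fragment length
#'
#' Single-end ChIP reads tag only fragment ends; each read is extended in
#' its strand's 3' direction from its 5' end to `target_length` bp total
#' (the 200 bp fragment-extension convention for 36 bp reads). Extensions
#' are clamped to chromosome bounds; read count is preserved.
#'
#' @param reads a `read_set`
#' @param genome a `genome_model`
#' @param target_length extended fragment length in bp (default 200); must
#'   be >= the longest observed read
#' @return a `read_set` of extended intervals
#' @export
extend_reads <- function(reads, genome, target_length = 200) {
  .check_genome(genome)
  if (nrow(reads) == 0L) return(reads)
  if (target_length < max(reads$end - reads$start))
    stop("`target_length` (", target_length,
         ") is shorter than an observed read")
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$start, reads$end - target_length)
  end <- ifelse(plus, reads$start + target_length, reads$end)
  lens <- .chrom_length(genome, reads$chrom)
  start <- pmax(start, 0)
  end <- pmin(end, lens)
  out <- reads
  out$start <- start
  out$end <- end
  out
}

#' Per-base-pair read pileup
#'
#' For each base pair, counts the number of intervals overlapping it, via
#' a difference-array cumulative sum (exact integer arithmetic). The total
#' signal equals the summed interval lengths, and the result is
#' independent of read order.
#'
#' @param intervals a `read_set` (typically extended reads)
#' @param genome a `genome_model`
#' @param sample_id label for the track (default: the read set's)
#' @return a raw `coverage_track`
#' @export
pileup <- function(intervals, genome, sample_id = NULL) {
  .check_genome(genome)
  if (is.null(sample_id))
    sample_id <- attr(intervals, "sample_id") %||% "sample"
  lens <- .chrom_length(genome, intervals$chrom)
  if (nrow(intervals) > 0 &&
      any(intervals$start < 0 | intervals$end > lens))
    stop("interval outside chromosome bounds")
  values <- lapply(stats::setNames(genome$chrom, genome$chrom), function(cn) {
    len <- genome$length[genome$chrom == cn]
    sel <- intervals$chrom == cn
    if (!any(sel)) return(numeric(len))
    delta <- tabulate(intervals$start[sel] + 1L, nbins = len) -
      tabulate(pmin(intervals$end[sel] + 1L, len + 1L), nbins = len + 1L)[seq_len(len)]
    # ends at the chromosome edge never get their -1 inside [1, len]:
    # tabulate at len+1 handles them via the nbins = len + 1 slot above
    as.numeric(cumsum(delta))
  })
  coverage_track(values, genome, sample_id = sample_id,
                 normalization_state = "raw")
}

#' Genome-wide normalization median of a track
#'
#' The median read count across the genome is ill-defined at low depth
#' when most bases are zero. Method "nonzero" takes the median over
#' covered bases only; "all" the plain genome-wide median; "auto" (the
#' default) uses the genome-wide median when at least half the genome is
#' covered and the nonzero median otherwise.
#'
#' @param track a `coverage_track`
#' @param method "auto", "nonzero" or "all"
#' @return the normalization median (a single number)
#' @export
coverage_median <- function(track, method = c("auto", "nonzero", "all")) {
  method <- match.arg(method)
  v <- unlist(track$values, use.names = FALSE)
  covered <- mean(v > 0)
  if (method == "all" || (method == "auto" && covered >= 0.5))
    return(stats::median(v))
  stats::median(v[v > 0])
}

#' Scale tracks to a common genome-wide median
#'
#' Each track is multiplied by `target / its normalization median`, so
#' that afterwards all tracks share the same normalization median. With
#' `target = "common"` the target is the first track's median.
#'
#' @param tracks a list of raw `coverage_track`s (a single track is
#'   accepted and wrapped)
#' @param target a positive number, or "common"
#' @param method median method, see [coverage_median()]
#' @return a list of `median_scaled` tracks (same length as the input)
#' @export
median_scale <- function(tracks, target = "common",
                         method = c("auto", "nonzero", "all")) {
  method <- match.arg(method)
  single <- inherits(tracks, "coverage_track")
  if (single) tracks <- list(tracks)
  meds <- vapply(tracks, function(t) {
    v <- unlist(t$values, use.names = FALSE)
    if (all(v == 0)) stop("cannot scale an all-zero track (sample '",
                          t$sample_id, "')")
    coverage_median(t, method)
  }, 0)
  if (any(!is.finite(meds) | meds <= 0))
    stop("normalization median must be positive")
  tgt <- if (identical(target, "common")) meds[[1]] else as.numeric(target)
  if (tgt <= 0) stop("`target` must be positive")
  out <- Map(function(t, m) {
    f <- tgt / m
    t$values <- lapply(t$values, `*`, f)
    t$scale_factor <- t$scale_factor * f
    t$normalization_state <- "median_scaled"
    t
  }, tracks, meds)
  if (single) out[[1]] else out
}

#' Average replicate tracks base pair by base pair
#'
#' Replicates must all be `median_scaled` (scaling precedes averaging) and
#' share a genome.
#'
#' @param tracks list of `median_scaled` tracks
#' @param sample_id label for the averaged track
#' @return a `replicate_averaged` `coverage_track`
#' @export
average_replicates <- function(tracks, sample_id = NULL) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  if (length(tracks) < 1L) stop("need at least one track")
  states <- vapply(tracks, `[[`, "", "normalization_state")
  if (!all(states == "median_scaled"))
    stop("all tracks must be median_scaled before averaging (got: ",
         paste(unique(states), collapse = ", "), ")")
  g <- tracks[[1]]$genome
  if (!all(vapply(tracks, function(t) identical(t$genome, g), TRUE)))
    stop("tracks must share a genome")
  if (is.null(sample_id)) sample_id <- tracks[[1]]$sample_id
  k <- length(tracks)
  values <- lapply(stats::setNames(g$chrom, g$chrom), function(cn) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[cn]])) / k
  })
  coverage_track(values, g, sample_id = sample_id,
                 normalization_state = "replicate_averaged",
                 scale_factor = mean(vapply(tracks, `[[`, 0, "scale_factor")))
}

#' Full coverage construction: extend, pile up, scale, average
#'
#' Convenience wrapper running the standard chain over one sample's
#' replicate read sets.
#'
#' @param reads_list list of `read_set`s (one per replicate)
#' @param genome a `genome_model`
#' @param extend fragment extension length in bp (default 200)
#' @param target median-scaling target (default "common")
#' @param method median method
#' @param sample_id label for the final track
#' @return a `replicate_averaged` `coverage_track`
#' @export
build_coverage <- function(reads_list, genome, extend = 200,
                           target = "common",
                           method = c("auto", "nonzero", "all"),
                           sample_id = NULL) {
  if (inherits(reads_list, "read_set")) reads_list <- list(reads_list)
  raw <- lapply(reads_list, function(r)
    pileup(extend_reads(r, genome, extend), genome))
  scaled <- median_scale(raw, target = target, method = match.arg(method))
  average_replicates(scaled, sample_id = sample_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
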