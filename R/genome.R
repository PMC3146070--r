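#' Toy genome model
#'
#' A genome model is a set of named chromosomes with lengths and an
#' X/autosome flag. All package coordinates are 0-based, half-open;
#' converters sit at the I/O boundaries (BED is native).
#'
#' @param n_autosomes number of autosomes (>= 1), named "chrI", "chrII", ...
#' @param chrom_length length in bp of every chromosome (>= 10000)
#' @param include_X append a single X chromosome ("chrX")?
#' @return a `genome_model`: data.frame with columns `chrom`, `length`,
#'   `is_X`. Construction is deterministic (no randomness involved).
#' @examples
#' g <- toy_genome(5, 1e5, include_X = TRUE)
#' genome_size(g)
#' @export
toy_genome <- function(n_autosomes, chrom_length, include_X = TRUE) {
  if (!is.numeric(n_autosomes) || length(n_autosomes) != 1L || n_autosomes < 1)
    stop("`n_autosomes` must be a single number >= 1")
  if (!is.numeric(chrom_length) || length(chrom_length) != 1L ||
      chrom_length < 10000)
    stop("`chrom_length` must be a single length >= 10000 bp")
  n_autosomes <- as.integer(n_autosomes)
  roman <- as.character(utils::as.roman(seq_len(n_autosomes)))
  chrom <- paste0("chr", roman)
  is_x <- rep(FALSE, n_autosomes)
  if (isTRUE(include_X)) {
    chrom <- c(chrom, "chrX")
    is_x <- c(is_x, TRUE)
  }
  genome_model(chrom, rep(as.numeric(chrom_length), length(chrom)), is_x)
}

#' Construct a genome model from explicit chromosomes
#'
#' @param chrom character vector of unique chromosome names
#' @param length numeric vector of chromosome lengths (bp, > 0)
#' @param is_X logical vector flagging at most one X chromosome
#' @return a `genome_model` data.frame
#' @export
genome_model <- function(chrom, length, is_X = rep(FALSE, base::length(chrom))) {
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  if (sum(is_X) > 1L) stop("at most one chromosome may be flagged X")
  if (sum(!is_X) < 1L) stop("at least one autosome is required")
  g <- data.frame(chrom = as.character(chrom), length = as.numeric(length),
                  is_X = as.logical(is_X), stringsAsFactors = FALSE)
  class(g) <- c("genome_model", "data.frame")
  g
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome model: %d chromosomes, %s bp total%s\n",
              nrow(x), format(genome_size(x), big.mark = ","),
              if (any(x$is_X)) sprintf(" (X: %s)", x$chrom[x$is_X]) else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Total genome size in bp
#' @param genome a `genome_model`
#' @export
genome_size <- function(genome) sum(genome$length)

#' Named vector of chromosome lengths
#' @param genome a `genome_model`
#' @export
chrom_lengths <- function(genome) stats::setNames(genome$length, genome$chrom)

.check_genome <- function(genome) {
  if (!inherits(genome, "genome_model")) stop("expected a `genome_model`")
  invisible(genome)
}

.chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$length[i]
}
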