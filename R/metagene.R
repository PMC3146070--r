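#' Anchored metagene profile with confidence intervals
#'
#' Aligns genes at the TSS or TES, reads the track in strand-oriented
#' coordinates (upstream = 5' of the gene; the window is reversed on "-"
#' strand genes), averages signal per gene within fixed bins, and then
#' reports across genes the mean with a 95% confidence interval per bin.
#' Default geometry follows the standard embryo ChIP-seq convention:
#' 50 bp bins, TSS window 1 kb upstream to 1.5 kb downstream, TES window
#' 1.5 kb upstream to 1 kb downstream (50 bins either way).
#'
#' Bin `i` covers strand-oriented offsets `[i*bin, (i+1)*bin)`; the anchor
#' sits at offset 0 and upstream bins are negative. The window is anchored,
#' not clipped to the gene, so short genes still contribute every bin;
#' only bins extending past a chromosome edge drop that gene (its `n`
#' decrements).
#'
#' @param track a `coverage_track`
#' @param genes a `gene_annotation`
#' @param geneset optional character vector of gene ids (default: all)
#' @param anchor "tss" or "tes"
#' @param upstream,downstream window extents in bp (defaults 1000/1500 at
#'   the TSS, 1500/1000 at the TES); must be multiples of `bin`
#' @param bin bin width in bp (default 50)
#' @param ci "normal" for mean +/- 1.96 * SD/sqrt(n) (default) or "t" for
#'   a Student-t interval; a single gene gives half-width 0 by convention
#' @return a `metagene_profile`: data.frame with `offset` (bin start
#'   relative to the anchor), `mean`, `ci_lo`, `ci_hi`, `n`; attributes
#'   `anchor`, `bin`, `upstream`, `downstream`
#' @export
metagene_profile <- function(track, genes, geneset = NULL,
                             anchor = c("tss", "tes"),
                             upstream = NULL, downstream = NULL, bin = 50,
                             ci = c("normal", "t")) {
  anchor <- match.arg(anchor)
  ci <- match.arg(ci)
  stopifnot(inherits(track, "coverage_track"))
  if (!inherits(genes, "gene_annotation")) genes <- gene_annotation(genes)
  if (is.null(upstream)) upstream <- if (anchor == "tss") 1000 else 1500
  if (is.null(downstream)) downstream <- if (anchor == "tss") 1500 else 1000
  if (bin <= 0) stop("`bin` must be > 0")
  if (upstream %% bin != 0 || downstream %% bin != 0)
    stop("`bin` must divide both window spans")
  if (!is.null(geneset)) {
    missing <- setdiff(geneset, genes$gene_id)
    if (length(missing))
      stop("geneset contains unknown genes: ",
           paste(utils::head(missing, 3), collapse = ", "))
    genes <- genes[genes$gene_id %in% geneset, , drop = FALSE]
  }
  if (nrow(genes) == 0L) stop("empty geneset")

  nbin <- as.integer((upstream + downstream) / bin)
  offsets <- seq(-upstream, downstream - bin, by = bin)
  anchors <- if (anchor == "tss") tss(genes) else tes(genes)
  # per-base strand-oriented offsets for one window
  rel <- seq(-upstream, downstream - 1)

  per_gene <- matrix(NA_real_, nrow(genes), nbin)
  for (i in seq_len(nrow(genes))) {
    a <- anchors[i]
    dir <- if (genes$strand[i] == "+") 1 else -1
    pos <- a + dir * rel                      # genomic, 0-based
    v <- track$values[[genes$chrom[i]]]
    inb <- pos >= 0 & pos < length(v)
    sig <- rep(NA_real_, length(pos))
    sig[inb] <- v[pos[inb] + 1]
    m <- matrix(sig, nrow = bin)              # columns = bins, 5'->3'
    ok <- colSums(is.na(m)) == 0
    per_gene[i, ok] <- colMeans(m[, ok, drop = FALSE])
  }

  n <- colSums(!is.na(per_gene))
  if (any(n == 0))
    stop("a bin has no contributing genes; shrink the window")
  mu <- colMeans(per_gene, na.rm = TRUE)
  sdv <- apply(per_gene, 2, stats::sd, na.rm = TRUE)
  sdv[n == 1] <- 0
  crit <- if (ci == "normal") rep(1.96, nbin) else
    ifelse(n > 1, stats::qt(0.975, n - 1), 0)
  half <- ifelse(n > 1, crit * sdv / sqrt(n), 0)
  out <- data.frame(offset = offsets, mean = mu, ci_lo = mu - half,
                    ci_hi = mu + half, n = n)
  attr(out, "anchor") <- anchor
  attr(out, "bin") <- bin
  attr(out, "upstream") <- upstream
  attr(out, "downstream") <- downstream
  attr(out, "sample_id") <- track$sample_id
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Per-bin difference between two metagene profiles
#'
#' Mean difference per bin with a pooled confidence interval (half-widths
#' combined in quadrature). Profiles must share anchor, window and bin
#' geometry.
#'
#' @param profile_a,profile_b `metagene_profile`s
#' @return data.frame with `offset`, `diff`, `ci_lo`, `ci_hi`
#' @export
profile_contrast <- function(profile_a, profile_b) {
  geom <- function(p) lapply(c("anchor", "bin", "upstream", "downstream"),
                             function(a) attr(p, a))
  if (!identical(geom(profile_a), geom(profile_b)))
    stop("profiles have mismatched anchor/window/bin geometry")
  d <- profile_a$mean - profile_b$mean
  ha <- (profile_a$ci_hi - profile_a$ci_lo) / 2
  hb <- (profile_b$ci_hi - profile_b$ci_lo) / 2
  half <- sqrt(ha^2 + hb^2)
  data.frame(offset = profile_a$offset, diff = d, ci_lo = d - half,
             ci_hi = d + half)
}

#' Plot a metagene profile
#'
#' Mean line with a shaded confidence band, anchor marked at offset 0.
#'
#' @param x a `metagene_profile`
#' @param col line colour
#' @param ... passed to [graphics::plot()]
#' @export
plot.metagene_profile <- function(x, col = "firebrick", ...) {
  xx <- x$offset + attr(x, "bin") / 2
  graphics::plot(xx, x$mean, type = "n",
                 xlab = sprintf("distance from %s (bp)",
                                toupper(attr(x, "anchor"))),
                 ylab = "mean signal",
                 ylim = range(x$ci_lo, x$ci_hi), ...)
  graphics::polygon(c(xx, rev(xx)), c(x$ci_lo, rev(x$ci_hi)),
                    col = grDevices::adjustcolor(col, 0.25), border = NA)
  graphics::lines(xx, x$mean, col = col, lwd = 2)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  invisible(x)
}
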