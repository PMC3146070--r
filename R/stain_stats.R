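#' Percent positive embryos, rounded as printed
#'
#' 100 * positive/total, rounded half away from zero to the nearest
#' integer — the convention consistent with published staining tables
#' (e.g. 3/35 = 8.57 -> 9 and 1/40 = 2.5 -> 3). The unrounded percentage
#' is returned alongside.
#'
#' @param positive count of positive embryos (vectorized)
#' @param total total embryos scored (> 0)
#' @return data.frame with `positive`, `total`, `percent_raw`, `percent`
#' @export
percent_positive <- function(positive, total) {
  if (any(total <= 0)) stop("`total` must be > 0")
  if (any(positive < 0 | positive > total))
    stop("`positive` must lie in [0, total]")
  raw <- 100 * positive / total
  data.frame(positive = positive, total = total, percent_raw = raw,
             percent = as.integer(floor(raw + 0.5)))
}

#' Wilson score confidence interval for a proportion
#'
#' @param positive successes (vectorized)
#' @param total trials (> 0)
#' @param level confidence level (default 0.95)
#' @return data.frame with `estimate`, `lower`, `upper`
#' @export
proportion_ci <- function(positive, total, level = 0.95) {
  if (any(total <= 0)) stop("`total` must be > 0")
  if (any(positive < 0 | positive > total))
    stop("`positive` must lie in [0, total]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- positive / total
  denom <- 1 + z^2 / total
  centre <- (p + z^2 / (2 * total)) / denom
  half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / denom
  data.frame(estimate = p, lower = pmax(centre - half, 0),
             upper = pmin(centre + half, 1))
}

#' Exact two-sided comparison of two staining proportions
#'
#' Fisher's exact test on the 2x2 positive/negative by genotype table.
#'
#' @param pos_a,tot_a counts for the first genotype
#' @param pos_b,tot_b counts for the second genotype
#' @return two-sided p-value
#' @export
compare_genotypes <- function(pos_a, tot_a, pos_b, tot_b) {
  tab <- matrix(c(pos_a, tot_a - pos_a, pos_b, tot_b - pos_b), nrow = 2)
  if (any(tab < 0)) stop("counts must satisfy 0 <= positive <= total")
  stats::fisher.test(tab)$p.value
}

#' Full staining report for a count table
#'
#' Per row: rounded and raw percent positive plus a Wilson interval; per
#' assay: Fisher's exact p-value of each genotype against the first
#' (reference) genotype.
#'
#' @param table data.frame with `genotype`, `assay`, `positive`, `total`
#'   (see [read_stain_table()])
#' @param level confidence level for the Wilson intervals
#' @return the table augmented with `percent`, `percent_raw`, `ci_lower`,
#'   `ci_upper`, `p_vs_reference`
#' @export
stain_report <- function(table, level = 0.95) {
  pp <- percent_positive(table$positive, table$total)
  ci <- proportion_ci(table$positive, table$total, level)
  out <- cbind(table, percent = pp$percent, percent_raw = pp$percent_raw,
               ci_lower = ci$lower, ci_upper = ci$upper)
  out$p_vs_reference <- NA_real_
  for (a in unique(out$assay)) {
    i <- which(out$assay == a)
    ref <- i[1]
    for (j in i)
      out$p_vs_reference[j] <- compare_genotypes(
        out$positive[j], out$total[j], out$positive[ref], out$total[ref])
  }
  out
}
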