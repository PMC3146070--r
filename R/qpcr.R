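#' ChIP-qPCR percent input
#'
#' Computes enrichment as the percentage of input chromatin recovered:
#'
#' \deqn{\%input = 100 \cdot b^{-\Delta Cp} \cdot
#'   \frac{df_{ChIP}}{df_{input}} \cdot \frac{f_{input}}{100}}
#'
#' with \eqn{\Delta Cp = Cp_{ChIP} - Cp_{input}}, amplification base
#' \eqn{b}, dilution factors \eqn{df}, and \eqn{f_{input}} the percentage
#' of the extract used as input. At \eqn{\Delta Cp = 0} and equal
#' dilutions the result is exactly the input fraction.
#'
#' Two conventions for the base are exposed: `"two_times_efficiency"`
#' (b = 2 * efficiency, the literal reading of the bench formula) and
#' `"one_plus_efficiency"` (b = 1 + efficiency, the common qPCR
#' convention where efficiency 1 means perfect doubling).
#'
#' @param cp_chip,cp_input crossing-point (Cp) cycle values
#' @param efficiency PCR efficiency in (0, 1]
#' @param df_chip,df_input dilution factors (>= 1)
#' @param input_fraction_percent percent of extract used as input, in
#'   (0, 100]
#' @param base amplification-base convention (see Details)
#' @return data.frame itemizing `delta_cp`, `base`, `dilution_ratio`,
#'   `input_fraction_percent`, and the final `percent_input`
#' @export
percent_input <- function(cp_chip, cp_input, efficiency = 1,
                          df_chip = 1, df_input = 1,
                          input_fraction_percent = 1,
                          base = c("two_times_efficiency",
                                   "one_plus_efficiency")) {
  base <- match.arg(base)
  if (any(!is.finite(cp_chip)) || any(!is.finite(cp_input)))
    stop("Cp values must be finite")
  if (any(efficiency <= 0) || any(efficiency > 1))
    stop("`efficiency` must be in (0, 1]")
  if (any(df_chip < 1) || any(df_input < 1))
    stop("dilution factors must be >= 1")
  if (any(input_fraction_percent <= 0) || any(input_fraction_percent > 100))
    stop("`input_fraction_percent` must be in (0, 100]")
  b <- if (base == "two_times_efficiency") 2 * efficiency else 1 + efficiency
  if (any(b <= 0)) stop("amplification base must be positive")
  delta <- cp_chip - cp_input
  if (any(b <= 1 & delta != 0))
    warning("amplification base <= 1: per-cycle gain is implausible")
  pct <- 100 * b^(-delta) * (df_chip / df_input) *
    (input_fraction_percent / 100)
  data.frame(delta_cp = delta, base = b,
             dilution_ratio = df_chip / df_input,
             input_fraction_percent = input_fraction_percent,
             percent_input = pct)
}

#' Percent input for a Cp table
#'
#' Pairs `chip` and `input` rows by `sample` (each sample needs exactly
#' one of each) and applies [percent_input()].
#'
#' @param table data.frame with `sample`, `Cp`, `dilution_factor`, `role`
#'   (see [read_qpcr_table()])
#' @param efficiency,input_fraction_percent,base as in [percent_input()]
#' @return data.frame, one row per sample, with the itemized components
#' @export
percent_input_table <- function(table, efficiency = 1,
                                input_fraction_percent = 1,
                                base = c("two_times_efficiency",
                                         "one_plus_efficiency")) {
  base <- match.arg(base)
  out <- lapply(split(table, table$sample), function(d) {
    chip <- d[d$role == "chip", ]
    inp <- d[d$role == "input", ]
    if (nrow(chip) != 1L || nrow(inp) != 1L)
      stop("sample '", d$sample[1],
           "' needs exactly one chip and one input row")
    cbind(sample = d$sample[1],
          percent_input(chip$Cp, inp$Cp, efficiency,
                        chip$dilution_factor, inp$dilution_factor,
                        input_fraction_percent, base))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
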