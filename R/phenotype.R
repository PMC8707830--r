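#' Water absorption rate
#'
#' Percentage water uptake of a seed lot relative to its dry weight:
#' `(W_a - W_b) / W_b * 100`, where `W_a` is the fresh weight before
#' drying and `W_b` the dry weight. Unit-free in the weight scale (grams
#' and milligrams give the same rate). A fresh weight below the dry weight
#' yields a negative rate with a warning (physically suspect but possible
#' with weighing noise).
#'
#' @param W_a fresh weight(s), same units as `W_b`.
#' @param W_b dry weight(s), must be positive.
#' @return water absorption rate in percent.
#' @examples
#' water_absorption_rate(1.3, 1.0)  # 30
#' @export
water_absorption_rate <- function(W_a, W_b) {
  if (any(W_b <= 0)) stop("dry weight W_b must be positive")
  if (any(W_a < W_b))
    warning("fresh weight below dry weight: negative absorption rate")
  (W_a - W_b) / W_b * 100
}

two_group_t <- function(xa, xb, var_equal = TRUE) {
  if (length(xa) < 2 || length(xb) < 2)
    stop("need at least 2 replicates per group")
  if (sd(xa) == 0 && sd(xb) == 0) {
    if (mean(xa) == mean(xb))
      return(list(t = 0, p = 1, degenerate = FALSE))
    return(list(t = sign(mean(xa) - mean(xb)) * Inf, p = 0,
                degenerate = TRUE))
  }
  ht <- t.test(xa, xb, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Compare germination between varieties at one time point
#'
#' Two-sided Student's t-test (pooled variance) of a phenotype value --
#' germination fraction by default -- between two varieties at a single
#' time point, with the conventional star coding (`*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001, otherwise `NS`). Swapping the variety order
#' flips the sign of `t` and leaves `p` unchanged.
#'
#' @param phenotype a phenotype table (see [read_phenotype()]) with one row
#'   per replicate.
#' @param timepoint time point (HAI) to test.
#' @param varieties the two varieties (default: the two present).
#' @param value which column to compare (default
#'   `"germination_fraction"`).
#' @param var_equal pooled-variance t-test (default `TRUE`).
#' @return a list: `variety_a`, `variety_b`, `mean_a`, `mean_b`,
#'   `t_statistic`, `p`, `stars`.
#' @export
compare_varieties <- function(phenotype, timepoint, varieties = NULL,
                              value = "germination_fraction",
                              var_equal = TRUE) {
  ph <- as.data.frame(phenotype)
  varieties <- varieties %||% unique(ph$variety)
  if (length(varieties) != 2) stop("exactly two varieties required")
  sel <- ph$timepoint_hai == timepoint
  xa <- ph[[value]][sel & ph$variety == varieties[1]]
  xb <- ph[[value]][sel & ph$variety == varieties[2]]
  ht <- two_group_t(xa, xb, var_equal)
  list(variety_a = varieties[1], variety_b = varieties[2],
       mean_a = mean(xa), mean_b = mean(xb),
       t_statistic = ht$t, p = ht$p, stars = p_stars(ht$p))
}

#' Treatment dose-response comparison of germination
#'
#' Compares each treatment level against the control series at each time
#' point by a two-sided Student's t-test on the replicate germination
#' fractions (the replicate dish is the unit of analysis), with star
#' coding. Any concentration grid is accepted and echoed as given.
#'
#' @param phenotype phenotype table with a `treatment` column; replicate
#'   rows per variety x time point x treatment.
#' @param control label of the control series (default `"CK"`).
#' @param varieties restrict to these varieties (default: all present).
#' @param timepoints restrict to these time points (default: all with
#'   treated data).
#' @param var_equal pooled-variance t-test (default `TRUE`).
#' @return tibble with one row per variety x treatment x time point:
#'   means of treated and control, `t_statistic`, `p`, `stars`.
#' @export
treatment_response <- function(phenotype, control = "CK",
                               varieties = NULL, timepoints = NULL,
                               var_equal = TRUE) {
  ph <- as.data.frame(phenotype)
  if (is.null(ph$treatment)) stop("phenotype table lacks 'treatment'")
  if (!any(ph$treatment == control))
    stop("control series '", control, "' not present")
  varieties <- varieties %||% unique(ph$variety)
  trts <- setdiff(unique(ph$treatment), control)
  rows <- list()
  for (v in varieties) {
    for (tr in trts) {
      tps <- timepoints %||%
        sort(unique(ph$timepoint_hai[ph$variety == v &
                                       ph$treatment == tr]))
      for (t in tps) {
        xa <- ph$germination_fraction[ph$variety == v &
                                        ph$treatment == tr &
                                        ph$timepoint_hai == t]
        xb <- ph$germination_fraction[ph$variety == v &
                                        ph$treatment == control &
                                        ph$timepoint_hai == t]
        if (!length(xa)) next
        if (!length(xb))
          stop("no control observations for ", v, " at ", t, " HAI")
        ht <- two_group_t(xa, xb, var_equal)
        rows[[length(rows) + 1]] <- tibble::tibble(
          variety = v, treatment = tr, timepoint_hai = t,
          mean_treated = mean(xa), mean_control = mean(xb),
          t_statistic = ht$t, p = ht$p, stars = p_stars(ht$p))
      }
    }
  }
  do.call(rbind, rows) %||%
    tibble::tibble(variety = character(), treatment = character(),
                   timepoint_hai = numeric(), mean_treated = numeric(),
                   mean_control = numeric(), t_statistic = numeric(),
                   p = numeric(), stars = character())
}
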