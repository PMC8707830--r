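#' Z-score standardization of a trajectory
#'
#' `(x - mean(x)) / sd(x)` with the sample standard deviation, applied to a
#' metabolite's per-time-point means. A constant profile has no shape; it
#' maps to all zeros (flagged downstream as flat).
#'
#' @param means numeric vector of per-time-point means.
#' @return z-scored vector of the same length (mean 0, sample SD 1 unless
#'   the input is constant).
#' @export
zscore_profile <- function(means) {
  s <- sd(means)
  if (is.na(s) || s == 0) return(rep(0, length(means)))
  (means - mean(means)) / s
}

#' Classify a standardized trajectory
#'
#' Assigns one of five pattern labels by the Spearman rank correlation of
#' the z-profile with time, with an interior-extremum fallback:
#' \itemize{
#'   \item `rho >= rho_threshold` -> `"accumulation"`;
#'   \item `rho <= -rho_threshold` -> `"consumption"`;
#'   \item otherwise, an interior maximum standing at least
#'     `prominence` z-units above both endpoints ->
#'     `"accumulation-then-consumption"` (interior minimum symmetric
#'     case -> `"consumption-then-accumulation"`);
#'   \item else `"flat"`.
#' }
#' The thresholds make the visual accumulation/consumption reading of a
#' trajectory heatmap reproducible; both are configurable.
#'
#' @param z_profile z-scored trajectory from [zscore_profile()].
#' @param timepoints time points (same length).
#' @param rho_threshold Spearman cutoff for a monotone call (default 0.6).
#' @param prominence minimal z-height of an interior extremum above/below
#'   both endpoints (default 1).
#' @return the label, with the trend statistic in `attr(, "rho")`.
#' @export
classify_trajectory <- function(z_profile, timepoints,
                                rho_threshold = 0.6, prominence = 1) {
  stopifnot(length(z_profile) == length(timepoints))
  if (all(z_profile == 0))
    return(structure("flat", rho = NA_real_))
  rho <- suppressWarnings(cor(z_profile, timepoints, method = "spearman"))
  label <- if (!is.na(rho) && rho >= rho_threshold) "accumulation"
    else if (!is.na(rho) && rho <= -rho_threshold) "consumption"
    else {
      n <- length(z_profile)
      imax <- which.max(z_profile)
      imin <- which.min(z_profile)
      edge_max <- max(z_profile[1], z_profile[n])
      edge_min <- min(z_profile[1], z_profile[n])
      if (imax > 1 && imax < n && z_profile[imax] - edge_max >= prominence)
        "accumulation-then-consumption"
      else if (imin > 1 && imin < n &&
               edge_min - z_profile[imin] >= prominence)
        "consumption-then-accumulation"
      else "flat"
    }
  structure(label, rho = rho)
}

#' Trajectory-pattern classification of metabolites
#'
#' Z-scores each metabolite's per-time-point mean trajectory and classifies
#' it with [classify_trajectory()]. Z-scores are computed per variety over
#' that variety's time points by default (each variety's trajectory row is
#' standardized on its own), or over both varieties' points jointly with
#' `basis = "combined"`.
#'
#' @param mat a (QC'd) [metabolome_matrix()].
#' @param metabolite_ids metabolites to classify (default: all).
#' @param basis `"per_variety"` (default) or `"combined"` z-score basis.
#' @param rho_threshold,prominence passed to [classify_trajectory()].
#' @param flat_cv profiles whose raw means vary by less than this
#'   coefficient of variation are labelled `"flat"` outright (default
#'   0.1): z-scoring normalizes away the scale, and without a flatness
#'   floor a trajectory that is pure replicate noise would be assigned a
#'   shape.
#' @return tibble with `metabolite_id`, `variety`, `label`, `trend_rho`;
#'   the long-format z-profiles (metabolite x variety x time point) are in
#'   `attr(, "profiles")`, ready for heatmap plotting.
#' @export
classify_patterns <- function(mat, metabolite_ids = NULL,
                              basis = c("per_variety", "combined"),
                              rho_threshold = 0.6, prominence = 1,
                              flat_cv = 0.1) {
  stopifnot(inherits(mat, "metabolome_matrix"))
  basis <- match.arg(basis)
  metabolite_ids <- metabolite_ids %||% colnames(mat$values)
  prof <- timepoint_profiles(mat)
  meta <- prof$meta
  vars <- unique(meta$variety)

  rows <- list()
  zlong <- list()
  for (m in metabolite_ids) {
    if (!(m %in% colnames(prof$values)))
      stop("metabolite not in matrix: ", m)
    if (basis == "combined") {
      zall <- zscore_profile(prof$values[, m])
    }
    for (v in vars) {
      sel <- which(meta$variety == v)
      sel <- sel[order(meta$timepoint_hai[sel])]
      tps <- meta$timepoint_hai[sel]
      raw <- prof$values[sel, m]
      z <- if (basis == "combined") zall[sel] else zscore_profile(raw)
      flatish <- mean(raw, na.rm = TRUE) > 0 &&
        sd(raw, na.rm = TRUE) / mean(raw, na.rm = TRUE) < flat_cv
      lab <- if (flatish) structure("flat", rho = NA_real_)
             else classify_trajectory(z, tps, rho_threshold, prominence)
      rows[[length(rows) + 1]] <-
        tibble::tibble(metabolite_id = m, variety = v,
                       label = as.character(lab),
                       trend_rho = attr(lab, "rho"))
      zlong[[length(zlong) + 1]] <-
        tibble::tibble(metabolite_id = m, variety = v,
                       timepoint_hai = tps, z = z)
    }
  }
  empty <- tibble::tibble(metabolite_id = character(),
                          variety = character(), label = character(),
                          trend_rho = numeric())
  out <- do.call(rbind, rows) %||% empty
  attr(out, "profiles") <- do.call(rbind, zlong) %||%
    tibble::tibble(metabolite_id = character(), variety = character(),
                   timepoint_hai = numeric(), z = numeric())
  attr(out, "basis") <- basis
  out
}
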