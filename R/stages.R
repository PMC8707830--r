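#' Per-time-point metabolome profiles
#'
#' Collapses replicates to one profile per variety x time point: the
#' replicate mean of each metabolite (missing-aware). With two varieties
#' and eight time points this yields 16 profiles. These profiles are the
#' unit of the stage analysis and of the correlation filter, matching a
#' design in which downstream statistics work on the average content of
#' the biological replicates.
#'
#' @param mat a (QC'd) [metabolome_matrix()].
#' @return a list of class `timepoint_profiles`: `values` (profiles x
#'   metabolites matrix, rownames `"variety@timepoint"`) and `meta`
#'   (tibble with `profile_id`, `variety`, `timepoint_hai`,
#'   `n_replicates`).
#' @export
timepoint_profiles <- function(mat) {
  stopifnot(inherits(mat, "metabolome_matrix"))
  smp <- mat$samples
  key <- paste0(smp$variety, "@", smp$timepoint_hai)
  meta <- unique(tibble::tibble(profile_id = key,
                                variety = smp$variety,
                                timepoint_hai = smp$timepoint_hai))
  meta <- meta[order(meta$variety, meta$timepoint_hai), ]
  vals <- matrix(NA_real_, nrow(meta), ncol(mat$values),
                 dimnames = list(meta$profile_id, colnames(mat$values)))
  n_rep <- integer(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    rows <- which(key == meta$profile_id[i])
    if (!length(rows))
      stop("empty variety x time point cell: ", meta$profile_id[i])
    n_rep[i] <- length(rows)
    vals[i, ] <- colMeans(mat$values[rows, , drop = FALSE], na.rm = TRUE)
  }
  vals[is.nan(vals)] <- NA_real_
  meta$n_replicates <- n_rep
  structure(list(values = vals, meta = meta), class = "timepoint_profiles")
}

#' Profile-profile Pearson correlation matrix
#'
#' Symmetric Pearson correlation matrix across the per-time-point
#' metabolome profiles (pairwise-complete over metabolites, raw
#' intensities), the quantity behind the clustered sample-correlation
#' heatmap of a two-variety time course. A constant profile has undefined
#' correlations; they are reported as `NA` with a warning, and the unit
#' diagonal is kept.
#'
#' @param profiles a [timepoint_profiles()] object.
#' @return a correlation matrix of class `profile_correlation` with the
#'   profile metadata attached as `attr(, "meta")`.
#' @export
profile_correlation <- function(profiles) {
  stopifnot(inherits(profiles, "timepoint_profiles"))
  if (nrow(profiles$values) < 2) stop("need at least 2 profiles")
  const <- apply(profiles$values, 1, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2 || sd(x) == 0
  })
  if (any(const))
    warning("constant profile(s), correlations undefined: ",
            paste(rownames(profiles$values)[const], collapse = ", "))
  cm <- suppressWarnings(cor(t(profiles$values),
                             use = "pairwise.complete.obs"))
  diag(cm) <- 1
  attr(cm, "meta") <- profiles$meta
  class(cm) <- c("profile_correlation", class(cm))
  cm
}

#' Order-constrained segmentation of a variety's time course into stages
#'
#' Segments one variety's time points into `k` contiguous stages by
#' constrained agglomeration: starting from one segment per time point,
#' repeatedly merge the adjacent pair of segments whose between-segment
#' mean Pearson correlation is highest, until `k` segments remain. Ties
#' break toward the earlier boundary. The contiguity constraint makes
#' "Stage I/II/III" well-defined: free hierarchical clustering of the same
#' correlations can interleave varieties or produce non-contiguous
#' clusters, which a developmental stage cannot be. The greedy merge also
#' makes segmentations nested across `k` (the boundaries at `k` contain
#' those at `k - 1`).
#'
#' @param cormat a [profile_correlation()] matrix.
#' @param variety which variety's profiles to segment.
#' @param k number of stages (default 3); `1 <= k <=` number of time
#'   points.
#' @return a list of class `stage_segmentation`: `stages` (list of
#'   time-point vectors), `boundaries` (last time point of each stage but
#'   the final one), `variety`, `k`, and `merge_trace` (the between-segment
#'   mean correlation consumed at each merge).
#' @export
segment_stages <- function(cormat, variety, k = 3) {
  stopifnot(inherits(cormat, "profile_correlation"))
  meta <- attr(cormat, "meta")
  sel <- which(meta$variety == variety)
  if (!length(sel)) stop("variety not present: ", variety)
  ord <- sel[order(meta$timepoint_hai[sel])]
  tps <- meta$timepoint_hai[ord]
  if (k < 1) stop("k must be >= 1")
  if (k > length(tps))
    stop("k exceeds the number of time points (", length(tps), ")")
  cm <- unclass(cormat)[ord, ord, drop = FALSE]

  segs <- as.list(seq_along(tps))
  trace <- numeric()
  while (length(segs) > k) {
    score <- vapply(seq_len(length(segs) - 1), function(i)
      mean(cm[segs[[i]], segs[[i + 1]], drop = FALSE], na.rm = TRUE),
      numeric(1))
    best <- which.max(score)  # ties -> earlier boundary
    trace <- c(trace, score[best])
    segs[[best]] <- c(segs[[best]], segs[[best + 1]])
    segs[[best + 1]] <- NULL
  }
  stages <- lapply(segs, function(ix) tps[ix])
  boundaries <- vapply(stages[-length(stages)], max, numeric(1))
  structure(list(stages = stages, boundaries = boundaries,
                 variety = variety, k = k, merge_trace = trace),
            class = "stage_segmentation")
}

#' @export
print.stage_segmentation <- function(x, ...) {
  cat("<stage_segmentation> ", x$variety, ", k = ", x$k, "\n", sep = "")
  for (i in seq_along(x$stages))
    cat("  Stage ", as.character(as.roman(i)), ": ",
        paste(x$stages[[i]], collapse = ", "), " HAI\n", sep = "")
  invisible(x)
}

#' Estimate the slow variety's developmental lag
#'
#' For each slow-variety time point `t`, finds the fast-variety time point
#' `s` whose metabolome profile correlates best with it and reports
#' `lag(t) = t - s` (ties toward the smaller `s`). The median lag over the
#' slow time points summarizes how far the slow variety's metabolome state
#' trails the fast one's.
#'
#' @param cormat a [profile_correlation()] matrix over both varieties.
#' @param fast,slow variety labels; by default the first and second variety
#'   present in the profile metadata.
#' @param segmentation optional [segment_stages()] result for the slow
#'   variety, used to add a per-stage median lag.
#' @return a list of class `lag_estimate`: `per_timepoint` (tibble with
#'   `timepoint_hai`, `best_match_hai`, `match_pcc`, `lag_hours`),
#'   `median_lag`, and (if a segmentation was given) `per_stage` median
#'   lags.
#' @export
estimate_lag <- function(cormat, fast = NULL, slow = NULL,
                         segmentation = NULL) {
  stopifnot(inherits(cormat, "profile_correlation"))
  meta <- attr(cormat, "meta")
  vars <- unique(meta$variety)
  if (length(vars) < 2) stop("two varieties required to estimate a lag")
  fast <- fast %||% vars[1]
  slow <- slow %||% vars[2]
  fi <- which(meta$variety == fast)
  si <- which(meta$variety == slow)
  fi <- fi[order(meta$timepoint_hai[fi])]
  si <- si[order(meta$timepoint_hai[si])]
  cm <- unclass(cormat)

  res <- lapply(si, function(s) {
    r <- cm[fi, s]
    best <- which(r == max(r, na.rm = TRUE))[1]  # ties -> smaller s
    tibble::tibble(timepoint_hai = meta$timepoint_hai[s],
                   best_match_hai = meta$timepoint_hai[fi][best],
                   match_pcc = r[best],
                   lag_hours = meta$timepoint_hai[s] -
                     meta$timepoint_hai[fi][best])
  })
  per_tp <- do.call(rbind, res)
  out <- list(per_timepoint = per_tp,
              median_lag = median(per_tp$lag_hours),
              fast = fast, slow = slow)
  if (!is.null(segmentation)) {
    stopifnot(inherits(segmentation, "stage_segmentation"))
    out$per_stage <- vapply(segmentation$stages, function(tps)
      median(per_tp$lag_hours[per_tp$timepoint_hai %in% tps]), numeric(1))
  }
  class(out) <- "lag_estimate"
  out
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat("<lag_estimate> ", x$slow, " relative to ", x$fast,
      "; median lag ", x$median_lag, " h\n", sep = "")
  print(x$per_timepoint)
  invisible(x)
}
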