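#' Replicate concordance quality control
#'
#' For every sample, the Pearson correlation of its metabolite vector
#' against each sibling replicate (same variety and time point) is computed
#' over pairwise-complete metabolites and averaged. Outliers are then
#' flagged cell by cell by greedy elimination: while the worst sample of a
#' cell has mean concordance to the remaining siblings below `threshold`
#' and more than two samples remain, it is flagged and concordance is
#' recomputed among the survivors. This captures the "one replicate quite
#' different from the other two" situation without condemning the two
#' concordant siblings, whose mean concordance the outlier also drags down.
#' A cell reduced to two discordant samples cannot be adjudicated; it is
#' warned about and left unflagged. Cells with a single replicate are
#' exempt (with a warning).
#'
#' The default threshold of 0.9 reflects that concordant LC-MS replicates
#' of the same seed pool typically correlate at 0.94 or above on the raw
#' intensity scale.
#'
#' @param mat a [metabolome_matrix()].
#' @param threshold minimum acceptable mean Pearson concordance (default
#'   0.9).
#' @return a tibble of class `replicate_qc` with one row per sample:
#'   `sample_id`, `variety`, `timepoint_hai`, `replicate`, `mean_pcc`
#'   (concordance to all siblings before any elimination) and `flagged`.
#'   Attributes: `threshold`, `removed` (empty; filled by
#'   [drop_flagged()]).
#' @export
replicate_concordance <- function(mat, threshold = 0.9) {
  stopifnot(inherits(mat, "metabolome_matrix"))
  smp <- mat$samples
  cell <- paste(smp$variety, smp$timepoint_hai)
  mean_pcc <- rep(NA_real_, nrow(smp))
  flagged <- rep(FALSE, nrow(smp))

  pair_cor <- function(i, j)
    suppressWarnings(cor(mat$values[i, ], mat$values[j, ],
                         use = "pairwise.complete.obs"))

  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    if (length(idx) < 2) {
      warning("variety x time point cell '", cl,
              "' has a single replicate; exempt from QC")
      next
    }
    cm <- matrix(1, length(idx), length(idx))
    for (a in seq_along(idx))
      for (b in seq_along(idx))
        if (a < b) cm[a, b] <- cm[b, a] <- pair_cor(idx[a], idx[b])
    mean_pcc[idx] <- (rowSums(cm, na.rm = TRUE) - 1) / (length(idx) - 1)

    active <- seq_along(idx)
    repeat {
      if (length(active) <= 2) {
        conc2 <- if (length(active) == 2) cm[active[1], active[2]] else 1
        if (length(active) == 2 && !is.na(conc2) && conc2 < threshold &&
            any(flagged[idx]))
          warning("cell '", cl, "' reduced to two discordant replicates; ",
                  "neither flagged")
        if (length(active) == 2 && !is.na(conc2) && conc2 < threshold &&
            !any(flagged[idx]))
          warning("cell '", cl, "' has only two, mutually discordant ",
                  "replicates; neither flagged")
        break
      }
      conc <- vapply(active, function(a)
        mean(cm[a, setdiff(active, a)], na.rm = TRUE), numeric(1))
      worst <- which.min(conc)
      if (is.na(conc[worst]) || conc[worst] >= threshold) break
      flagged[idx[active[worst]]] <- TRUE
      active <- active[-worst]
    }
  }

  out <- tibble::tibble(sample_id = smp$sample_id,
                        variety = smp$variety,
                        timepoint_hai = smp$timepoint_hai,
                        replicate = smp$replicate,
                        mean_pcc = mean_pcc,
                        flagged = flagged)
  attr(out, "threshold") <- threshold
  attr(out, "removed") <- character()
  class(out) <- c("replicate_qc", class(out))
  out
}

#' Drop replicates flagged by quality control
#'
#' Removal is deliberately a separate, opt-in step: silent data removal is
#' hazardous, so [replicate_concordance()] only reports and this function
#' performs the elimination, logging each removed sample.
#'
#' @param mat the [metabolome_matrix()] the report was computed from.
#' @param report a `replicate_qc` report from [replicate_concordance()].
#' @return the matrix without the flagged samples; the removed ids are
#'   recorded in `attr(, "removed")`.
#' @export
drop_flagged <- function(mat, report) {
  stopifnot(inherits(mat, "metabolome_matrix"),
            inherits(report, "replicate_qc"))
  if (!identical(sort(report$sample_id), sort(mat$samples$sample_id)))
    stop("QC report does not match the matrix: sample sets differ")
  drop_ids <- report$sample_id[report$flagged]
  if (!length(drop_ids)) return(mat)

  keep <- !(mat$samples$sample_id %in% drop_ids)
  kept <- mat$samples[keep, ]
  cells_all <- unique(paste(mat$samples$variety, mat$samples$timepoint_hai))
  cells_left <- paste(kept$variety, kept$timepoint_hai)
  emptied <- setdiff(cells_all, cells_left)
  if (length(emptied))
    stop("removal would leave variety x time point cell(s) with 0 ",
         "replicates: ", paste(emptied, collapse = "; "))
  message("QC removed ", length(drop_ids), " sample(s): ",
          paste(drop_ids, collapse = ", "))
  out <- subset_samples(mat, which(keep))
  attr(out, "removed") <- drop_ids
  out
}
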