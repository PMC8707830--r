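#' Pearson product-moment correlation
#'
#' Thin wrapper around the product-moment correlation with the pipeline's
#' missing policy (pairwise-complete) and degeneracy handling: fewer than
#' three complete pairs is an error, a constant series yields `NA` with a
#' warning (the caller excludes the metabolite with a logged reason).
#'
#' @param x,y numeric vectors of equal length.
#' @return the correlation coefficient, or `NA` if either series is
#'   constant.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    warning("constant series: correlation undefined")
    return(NA_real_)
  }
  cor(x[ok], y[ok])
}

#' Two-sided p-value of a Pearson correlation
#'
#' The t-transform used by the standard correlation test:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a t distribution with
#' `n - 2` degrees of freedom, two-sided. `|r| = 1` is degenerate; 0 is
#' returned with attribute `degenerate = TRUE`.
#'
#' @param r correlation coefficient.
#' @param n number of paired observations (`>= 3`).
#' @return the two-sided p-value.
#' @examples
#' correlation_pvalue(0.94, 6)   # ~0.005
#' correlation_pvalue(-0.95, 6)  # ~0.004
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 3) stop("n must be >= 3")
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1)
    return(structure(0, degenerate = TRUE))
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
}

germination_rate_at <- function(phenotype, variety, timepoints) {
  ph <- as.data.frame(phenotype)
  if (!is.null(ph$treatment))
    ph <- ph[is.na(ph$treatment) | ph$treatment %in% c("CK", "control"), ]
  ph <- ph[ph$variety == variety, ]
  vapply(timepoints, function(t) {
    g <- ph$germination_fraction[ph$timepoint_hai == t]
    if (!length(g)) return(NA_real_)
    mean(g, na.rm = TRUE)
  }, numeric(1))
}

#' Correlation filter (COR): metabolite content vs germination rate
#'
#' For each metabolite and variety, correlates the per-time-point replicate
#' mean content with the variety's germination rate over the tested time
#' points (default 6-48 HAI, when germination is underway), computes the
#' two-sided p-value by the t-transform (equivalent to the standard
#' Pearson correlation test), and flags the edge as passing when
#' `p < alpha` and `|r| > r_min`. Metabolites with a constant mean series
#' are excluded with a logged reason (attribute `excluded`).
#'
#' @param mat a (QC'd) [metabolome_matrix()].
#' @param phenotype a germination phenotype table (see [read_phenotype()]);
#'   germination rates are replicate-averaged per variety x time point.
#' @param varieties varieties to screen (default: all in `mat`).
#' @param timepoints time points used for the correlation (default
#'   `c(6, 9, 12, 24, 36, 48)`).
#' @param alpha significance threshold on the p-value (default 0.05).
#' @param r_min minimum `|r|` (default 0.8).
#' @return tibble of correlation edges with columns `metabolite_id`,
#'   `variety`, `r`, `n`, `t_statistic`, `p`, `passes`; excluded
#'   metabolites in `attr(, "excluded")`.
#' @export
cor_screen <- function(mat, phenotype, varieties = NULL,
                       timepoints = c(6, 9, 12, 24, 36, 48),
                       alpha = 0.05, r_min = 0.8) {
  stopifnot(inherits(mat, "metabolome_matrix"))
  varieties <- varieties %||% unique(mat$samples$variety)
  prof <- timepoint_profiles(mat)

  edges <- list()
  excluded <- list()
  for (v in varieties) {
    g <- germination_rate_at(phenotype, v, timepoints)
    if (anyNA(g))
      stop("missing germination rate for variety '", v, "' at time ",
           "point(s): ", paste(timepoints[is.na(g)], collapse = ", "))
    pid <- paste0(v, "@", timepoints)
    if (!all(pid %in% rownames(prof$values)))
      stop("matrix lacks variety '", v, "' at time point(s): ",
           paste(timepoints[!(pid %in% rownames(prof$values))],
                 collapse = ", "))
    pm <- prof$values[pid, , drop = FALSE]
    if (sd(g) == 0) stop("germination rate is constant for '", v, "'")
    for (m in colnames(pm)) {
      x <- pm[, m]
      ok <- !is.na(x)
      if (sum(ok) < 3) {
        excluded[[length(excluded) + 1]] <-
          tibble::tibble(metabolite_id = m, variety = v,
                         reason = "fewer than 3 complete time points")
        next
      }
      if (sd(x[ok]) == 0) {
        excluded[[length(excluded) + 1]] <-
          tibble::tibble(metabolite_id = m, variety = v,
                         reason = "constant content series")
        next
      }
      r <- cor(x[ok], g[ok])
      n <- sum(ok)
      t_stat <- if (abs(r) < 1) r * sqrt(n - 2) / sqrt(1 - r^2)
                else sign(r) * Inf
      p <- correlation_pvalue(r, n)
      edges[[length(edges) + 1]] <-
        tibble::tibble(metabolite_id = m, variety = v, r = r, n = n,
                       t_statistic = t_stat, p = as.numeric(p),
                       passes = (p < alpha) && (abs(r) > r_min))
    }
  }
  out <- do.call(rbind, edges) %||%
    tibble::tibble(metabolite_id = character(), variety = character(),
                   r = numeric(), n = integer(), t_statistic = numeric(),
                   p = numeric(), passes = logical())
  attr(out, "excluded") <- do.call(rbind, excluded) %||%
    tibble::tibble(metabolite_id = character(), variety = character(),
                   reason = character())
  attr(out, "alpha") <- alpha
  attr(out, "r_min") <- r_min
  out
}

#' Coefficient of variation
#'
#' `sd(x) / mean(x)` with the sample (n - 1) standard deviation. Undefined
#' for non-positive mean: returns `NA` with a warning so the caller can
#' exclude the metabolite with a logged reason.
#'
#' @param x numeric vector, length `>= 2` after removing `NA`.
#' @return the coefficient of variation.
#' @examples
#' cv(c(1, 2, 3))  # 0.5
#' @export
cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 values")
  mu <- mean(x)
  if (mu <= 0) {
    warning("non-positive mean: CV undefined")
    return(NA_real_)
  }
  sd(x) / mu
}

#' Coefficient-of-variation filter (CV)
#'
#' Flags, per variety, metabolites whose content fluctuates over the
#' germination course: the CV across the per-time-point replicate means
#' (default basis) exceeds `threshold` (default 0.30, i.e. 30%). A
#' `"replicates"` basis computing the CV over all replicate-level values is
#' available.
#'
#' @param mat a (QC'd) [metabolome_matrix()].
#' @param varieties varieties to screen (default: all).
#' @param threshold CV cutoff (default 0.30).
#' @param basis `"means"` (CV over per-time-point means, default) or
#'   `"replicates"` (CV over all replicate values).
#' @return tibble with `metabolite_id`, `variety`, `cv`, `passes`;
#'   excluded metabolites (undefined CV) in `attr(, "excluded")`.
#' @export
cv_screen <- function(mat, varieties = NULL, threshold = 0.30,
                      basis = c("means", "replicates")) {
  stopifnot(inherits(mat, "metabolome_matrix"))
  basis <- match.arg(basis)
  varieties <- varieties %||% unique(mat$samples$variety)
  prof <- if (basis == "means") timepoint_profiles(mat) else NULL

  rows <- list()
  excluded <- list()
  for (v in varieties) {
    vm <- if (basis == "means") {
      prof$values[prof$meta$variety == v, , drop = FALSE]
    } else {
      mat$values[mat$samples$variety == v, , drop = FALSE]
    }
    for (m in colnames(vm)) {
      x <- vm[, m]
      x <- x[!is.na(x)]
      if (length(x) < 2 || mean(x) <= 0) {
        excluded[[length(excluded) + 1]] <-
          tibble::tibble(metabolite_id = m, variety = v,
                         reason = if (length(x) < 2) "fewer than 2 values"
                                  else "non-positive mean")
        next
      }
      cvi <- sd(x) / mean(x)
      rows[[length(rows) + 1]] <-
        tibble::tibble(metabolite_id = m, variety = v, cv = cvi,
                       passes = cvi > threshold)
    }
  }
  out <- do.call(rbind, rows) %||%
    tibble::tibble(metabolite_id = character(), variety = character(),
                   cv = numeric(), passes = logical())
  attr(out, "excluded") <- do.call(rbind, excluded) %||%
    tibble::tibble(metabolite_id = character(), variety = character(),
                   reason = character())
  attr(out, "threshold") <- threshold
  attr(out, "basis") <- basis
  out
}

#' Differential accumulation filter (DAM)
#'
#' Compares the two varieties metabolite by metabolite at each tested time
#' point (default 6-48 HAI): a two-sided two-sample Student's t-test
#' (equal variance; Welch via `var_equal = FALSE`) on the replicate values,
#' and a fold change computed from the replicate means (larger over
#' smaller, with the direction recorded) after adding a pseudo-count to
#' both means to guard zero. P-values are Benjamini-Hochberg adjusted
#' within each time point across metabolites, and a record is significant
#' when the fold change exceeds `fc_min` and the gated p-value (adjusted by
#' default, raw via `gate = "raw"`) is below `alpha`. A metabolite with
#' any missing replicate in either group at a time point is dropped from
#' that test. Zero variance in both groups is degenerate: equal means give
#' p = 1, unequal means give p = 0 with `degenerate = TRUE`.
#'
#' @param mat a (QC'd) [metabolome_matrix()] with exactly two varieties
#'   present (or `varieties` given).
#' @param varieties the two varieties to compare (default: the two in
#'   `mat`).
#' @param timepoints time points tested (default `c(6, 9, 12, 24, 36, 48)`).
#' @param fc_min fold-change threshold (default 2).
#' @param alpha significance threshold (default 0.05).
#' @param gate `"adjusted"` (BH-adjusted p gates significance, default) or
#'   `"raw"`.
#' @param var_equal use the pooled-variance Student's t-test (default
#'   `TRUE`).
#' @param pseudo pseudo-count added to both means for the fold change;
#'   default half the smallest positive value in the matrix.
#' @return tibble of class `dam_screen` with one row per metabolite x time
#'   point: means of both varieties, `fold_change`, `higher_in`, `raw_p`,
#'   `adjusted_p`, `significant`, `degenerate`. The union set of
#'   significant metabolites is in `attr(, "dam_set")`; [dam_set()]
#'   retrieves it.
#' @export
dam_screen <- function(mat, varieties = NULL,
                       timepoints = c(6, 9, 12, 24, 36, 48),
                       fc_min = 2, alpha = 0.05,
                       gate = c("adjusted", "raw"),
                       var_equal = TRUE, pseudo = NULL) {
  stopifnot(inherits(mat, "metabolome_matrix"))
  gate <- match.arg(gate)
  varieties <- varieties %||% unique(mat$samples$variety)
  if (length(varieties) != 2)
    stop("DAM needs exactly two varieties; got ",
         paste(varieties, collapse = ", "))
  pos <- mat$values[mat$values > 0 & !is.na(mat$values)]
  pseudo <- pseudo %||% (if (length(pos)) min(pos) * 0.5 else 0)

  smp <- mat$samples
  rows <- list()
  for (t in timepoints) {
    ia <- which(smp$variety == varieties[1] & smp$timepoint_hai == t)
    ib <- which(smp$variety == varieties[2] & smp$timepoint_hai == t)
    if (length(ia) < 2 || length(ib) < 2)
      stop("fewer than 2 replicates at ", t, " HAI for ",
           if (length(ia) < 2) varieties[1] else varieties[2])
    res <- lapply(colnames(mat$values), function(m) {
      xa <- mat$values[ia, m]
      xb <- mat$values[ib, m]
      if (anyNA(xa) || anyNA(xb))
        return(tibble::tibble(metabolite_id = m, timepoint_hai = t,
                              mean_a = NA_real_, mean_b = NA_real_,
                              fold_change = NA_real_,
                              higher_in = NA_character_,
                              raw_p = NA_real_, degenerate = FALSE))
      ma <- mean(xa); mb <- mean(xb)
      fc <- (max(ma, mb) + pseudo) / (min(ma, mb) + pseudo)
      hi <- if (ma >= mb) varieties[1] else varieties[2]
      degen <- FALSE
      if (sd(xa) == 0 && sd(xb) == 0) {
        p <- if (ma == mb) 1 else {degen <- TRUE; 0}
      } else {
        p <- t.test(xa, xb, var.equal = var_equal)$p.value
      }
      tibble::tibble(metabolite_id = m, timepoint_hai = t,
                     mean_a = ma, mean_b = mb, fold_change = fc,
                     higher_in = hi, raw_p = p, degenerate = degen)
    })
    tpres <- do.call(rbind, res)
    tpres$adjusted_p <- NA_real_
    ok <- !is.na(tpres$raw_p)
    tpres$adjusted_p[ok] <- p.adjust(tpres$raw_p[ok], method = "BH")
    gate_p <- if (gate == "adjusted") tpres$adjusted_p else tpres$raw_p
    tpres$significant <- !is.na(gate_p) & gate_p < alpha &
      !is.na(tpres$fold_change) & tpres$fold_change > fc_min
    rows[[length(rows) + 1]] <- tpres
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", varieties[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", varieties[2])
  attr(out, "dam_set") <-
    sort(unique(out$metabolite_id[out$significant]))
  attr(out, "varieties") <- varieties
  attr(out, "fc_min") <- fc_min
  attr(out, "alpha") <- alpha
  attr(out, "gate") <- gate
  attr(out, "pseudo") <- pseudo
  class(out) <- c("dam_screen", class(out))
  out
}

#' @rdname dam_screen
#' @param records a `dam_screen` result.
#' @export
dam_set <- function(records) attr(records, "dam_set")

#' Intersect the three candidate filters
#'
#' Combines the correlation (COR), coefficient-of-variation (CV) and
#' differential-accumulation (DAM) filters into the final candidate set:
#' per-method sets are first combined across varieties (union by default:
#' a metabolite germination-linked in either variety counts; strict
#' `"intersection"` mode available), then the three method sets are
#' intersected. Per-class counts of the candidates are computed from the
#' annotations.
#'
#' @param cor_edges result of [cor_screen()].
#' @param cv_results result of [cv_screen()] covering both varieties.
#' @param dam_records result of [dam_screen()].
#' @param annotations optional metabolite annotation table with
#'   `metabolite_id` and `compound_class` (defaults to class "others").
#' @param combine `"union"` (default) or `"intersection"` across varieties
#'   for the COR and CV filters.
#' @return a list of class `screening_result`: per-method sets
#'   (`cor_set`, `cv_set`, `dam_set`), per-variety subsets, the candidate
#'   `candidates` vector, `class_counts`, and the thresholds used.
#' @export
intersect_screens <- function(cor_edges, cv_results, dam_records,
                              annotations = NULL,
                              combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  universe_cor <- sort(unique(c(cor_edges$metabolite_id,
                                attr(cor_edges, "excluded")$metabolite_id)))
  universe_cv <- sort(unique(c(cv_results$metabolite_id,
                               attr(cv_results, "excluded")$metabolite_id)))
  universe_dam <- sort(unique(dam_records$metabolite_id))
  if (!identical(universe_cor, universe_cv) ||
      !identical(universe_cor, universe_dam))
    stop("universe mismatch: the three filters were not computed on the ",
         "same metabolite set")

  per_var_sets <- function(tbl) {
    split(tbl$metabolite_id[tbl$passes], tbl$variety[tbl$passes])
  }
  combine_sets <- function(sets, all_vars) {
    sets <- lapply(all_vars, function(v) sets[[v]] %||% character())
    if (combine == "union") sort(unique(unlist(sets)))
    else sort(Reduce(intersect, sets))
  }
  vars <- sort(unique(c(cor_edges$variety, cv_results$variety)))
  cor_by_var <- per_var_sets(cor_edges)
  cv_by_var <- per_var_sets(cv_results)
  cor_set <- combine_sets(cor_by_var, vars)
  cv_set <- combine_sets(cv_by_var, vars)
  dset <- dam_set(dam_records)

  candidates <- sort(Reduce(intersect, list(cor_set, cv_set, dset)))

  if (is.null(annotations))
    annotations <- data.frame(metabolite_id = universe_cor,
                              compound_class = "others",
                              stringsAsFactors = FALSE)
  ann <- as.data.frame(annotations)
  cls <- ann$compound_class[match(candidates, ann$metabolite_id)]
  cls[is.na(cls)] <- "others"
  class_counts <- if (length(candidates)) sort(table(cls), decreasing = TRUE)
                  else table(character())

  structure(list(cor_set = cor_set, cv_set = cv_set, dam_set = dset,
                 candidates = candidates,
                 per_variety = list(cor = cor_by_var, cv = cv_by_var),
                 class_counts = class_counts,
                 combine = combine,
                 thresholds = list(
                   alpha = attr(cor_edges, "alpha"),
                   r_min = attr(cor_edges, "r_min"),
                   cv_min = attr(cv_results, "threshold"),
                   cv_basis = attr(cv_results, "basis"),
                   fc_min = attr(dam_records, "fc_min"),
                   dam_alpha = attr(dam_records, "alpha"),
                   dam_gate = attr(dam_records, "gate"))),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> (", x$combine, " across varieties)\n", sep = "")
  cat("  COR: ", length(x$cor_set), "  CV: ", length(x$cv_set),
      "  DAM: ", length(x$dam_set), "\n", sep = "")
  cat("  candidates (COR ∩ CV ∩ DAM): ", length(x$candidates),
      "\n", sep = "")
  if (length(x$candidates)) {
    cat("  classes:\n")
    print(x$class_counts)
  }
  invisible(x)
}
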