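#' Configuration for the synthetic germination metabolome generator
#'
#' Bundles every knob of [generate_dataset()] with the defaults that emulate
#' the study design the pipeline targets: two rice varieties (one fast, one
#' slow germinator), eight sampling points at 0/3/6/9/12/24/36/48 hours
#' after imbibition (HAI), three biological replicates, about 400 annotated
#' metabolites of which a planted subset tracks the germination curve, and
#' multiplicative log-normal replicate noise typical of LC-MS intensities.
#'
#' Germination is modelled as a logistic curve of time; the slow variety's
#' curve is the fast variety's shifted right by `lag_hours`, and every
#' metabolite trajectory runs on the variety's developmental clock
#' `u = t - lag`. A planted "associated" metabolite follows a switch-like
#' response in developmental time: its mean is
#' `base * (1 + beta * p(u))` (accumulation) or
#' `base * (1 + beta * (1 - p(u)))` (consumption), where `p` is a logistic
#' response with a metabolite-specific midpoint and steepness
#' (`response_midpoint_range`, `response_steepness_range`) and the
#' amplitude `beta` is drawn from `effect_range` and shared by both
#' varieties. Varieties thus have identical dry-seed metabolomes and
#' identical endpoint chemistry -- as near-isogenic germination contrasts
#' do -- and all between-variety differential accumulation is transient,
#' created by the developmental lag crossing a metabolite's response
#' window (with `association_link = "linear"` the response is the
#' germination curve itself, an exactly affine link useful for analytical
#' checks). Background (non-associated) metabolites are mostly flat, with
#' a minority following saturating imbibition-response ramps (half-times
#' spread over 3-24 h) or an interior-peak bump, again on the
#' developmental clock with one shared baseline, so the metabolome state
#' evolves from the first hours of imbibition onward as in real
#' germinating seeds.
#'
#' @param n_metabolites total number of metabolites (default 400).
#' @param n_associated number of planted germination-associated metabolites
#'   (default 60).
#' @param class_proportions named numeric vector over compound classes,
#'   summing to 1.
#' @param archetype_mix named proportions over trajectory archetypes for
#'   associated metabolites (`accumulation`, `consumption`); must sum to 1.
#' @param background_mix named proportions over background archetypes
#'   (`flat`, `accumulation`, `consumption`,
#'   `accumulation-then-consumption`); must sum to 1.
#' @param timepoints sampling grid in HAI.
#' @param n_replicates biological replicates per variety x time point.
#' @param varieties two labels, fast germinator first.
#' @param lag_hours right shift (h) of the slow variety's curves; default
#'   12, the mid-course metabolome separation typical of a slow japonica
#'   relative to a fast indica (the early-course separation is smaller,
#'   about 6 h, and can be set instead).
#' @param noise_cv target coefficient of variation of replicate noise
#'   (default 0.15). For the log-normal model the log-sd is
#'   `sqrt(log(1 + noise_cv^2))` so that the population CV equals
#'   `noise_cv` exactly.
#' @param noise_model `"lognormal"` (multiplicative, default) or
#'   `"additive"` (Gaussian with sd `noise_cv * mean`).
#' @param n_outlier_replicates number of replicate samples replaced by an
#'   unrelated profile (metabolite labels permuted), default 0.
#' @param germination_midpoint,germination_steepness logistic midpoint and
#'   scale (h) of the fast variety's germination curve.
#' @param effect_range range of the associated-metabolite amplitude
#'   (multiplicative modulation depth, shared by both varieties).
#' @param association_link `"sigmoid"` (default): each associated
#'   metabolite has its own logistic response in developmental time;
#'   `"linear"`: the response is the variety's germination curve itself,
#'   making the mean exactly affine in the germination fraction.
#' @param response_midpoint_range,response_steepness_range ranges (h) of
#'   the per-metabolite response midpoint and steepness under the sigmoid
#'   link.
#' @param stage_regimes optional numeric vector of internal stage
#'   boundaries in HAI (e.g. `c(12, 36)`). When set, a fraction
#'   `regime_fraction` of the background metabolites take piecewise-constant
#'   stage-specific levels (on the fast variety's clock; the slow variety is
#'   lagged), planting sharp metabolome stage boundaries.
#' @param regime_fraction fraction of background metabolites made
#'   stage-structured when `stage_regimes` is set (default 0.7).
#' @param regime_level_sdlog log-sd of the stage-specific level
#'   multipliers of regime-structured metabolites (default 1.6): the
#'   between-stage contrast that makes stage boundaries visible in the
#'   global correlation structure.
#' @param seeds_per_dish seeds per replicate dish used for binomial
#'   germination counts (default 50).
#' @param rng_seed integer seed; identical seed + config give identical
#'   output.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_metabolites = 400L,
                             n_associated = 60L,
                             class_proportions = c(
                               "lipids" = 0.25,
                               "flavonoids" = 0.18,
                               "amino acids and derivatives" = 0.17,
                               "polyamines" = 0.04,
                               "organic acids" = 0.06,
                               "terpenes" = 0.05,
                               "nucleotides and derivatives" = 0.05,
                               "phytohormones" = 0.03,
                               "sugars" = 0.04,
                               "vitamins and derivatives" = 0.06,
                               "others" = 0.07),
                             archetype_mix = c("accumulation" = 0.7,
                                               "consumption" = 0.3),
                             background_mix = c(
                               "flat" = 0.75,
                               "accumulation" = 0.10,
                               "consumption" = 0.10,
                               "accumulation-then-consumption" = 0.05),
                             timepoints = c(0, 3, 6, 9, 12, 24, 36, 48),
                             n_replicates = 3L,
                             varieties = c("fast", "slow"),
                             lag_hours = 12,
                             noise_cv = 0.15,
                             noise_model = c("lognormal", "additive"),
                             n_outlier_replicates = 0L,
                             germination_midpoint = 15,
                             germination_steepness = 4,
                             effect_range = c(3, 5),
                             association_link = c("sigmoid", "linear"),
                             response_midpoint_range = c(6, 11),
                             response_steepness_range = c(1.2, 2),
                             stage_regimes = NULL,
                             regime_fraction = 0.7,
                             regime_level_sdlog = 1.6,
                             seeds_per_dish = 50L,
                             rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  association_link <- match.arg(association_link)
  stopifnot(n_metabolites >= 1, n_associated >= 0,
            n_associated <= n_metabolites,
            lag_hours >= 0, noise_cv >= 0, n_replicates >= 1,
            length(varieties) == 2, n_outlier_replicates >= 0,
            regime_fraction >= 0, regime_fraction <= 1)
  for (nm in c("class_proportions", "archetype_mix", "background_mix")) {
    p <- get(nm)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(nm, " must be non-negative and sum to 1 (got ", sum(p), ")")
  }
  if (!is.null(stage_regimes)) {
    stage_regimes <- sort(stage_regimes)
    if (!all(stage_regimes %in% timepoints))
      stop("stage_regimes must be drawn from the time-point grid")
  }
  cfg <- list(n_metabolites = as.integer(n_metabolites),
              n_associated = as.integer(n_associated),
              class_proportions = class_proportions,
              archetype_mix = archetype_mix,
              background_mix = background_mix,
              timepoints = sort(unique(timepoints)),
              n_replicates = as.integer(n_replicates),
              varieties = as.character(varieties),
              lag_hours = lag_hours,
              noise_cv = noise_cv,
              noise_model = noise_model,
              n_outlier_replicates = as.integer(n_outlier_replicates),
              germination_midpoint = germination_midpoint,
              germination_steepness = germination_steepness,
              effect_range = effect_range,
              association_link = association_link,
              response_midpoint_range = response_midpoint_range,
              response_steepness_range = response_steepness_range,
              stage_regimes = stage_regimes,
              regime_fraction = regime_fraction,
              regime_level_sdlog = regime_level_sdlog,
              seeds_per_dish = as.integer(seeds_per_dish),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Logistic germination curve
#'
#' Germination fraction at time `t` (HAI) for the generator's model:
#' `plogis((t - lag - midpoint)/steepness)`.
#'
#' @param t time in HAI.
#' @param config a [synthetic_config()].
#' @param lag right shift in hours (0 for the fast variety).
#' @return germination fraction in (0, 1).
#' @export
germination_curve <- function(t, config, lag = 0) {
  stats::plogis((t - lag - config$germination_midpoint) /
                  config$germination_steepness)
}

# allocate counts to categories by largest remainder so they sum to n
allocate_counts <- function(n, props) {
  raw <- props * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

# piecewise-constant triphasic water-uptake curve (% of dry weight)
uptake_curve <- function(t, lag = 0) {
  u <- pmax(t - lag, 0)
  25 * pmin(u, 12) / 12 +
    5 * pmin(pmax((u - 12) / 24, 0), 1) +
    15 * pmin(pmax((u - 36) / 12, 0), 1)
}

#' Generate a synthetic germination metabolome dataset
#'
#' Draws a complete study -- intensity matrix, germination/water-uptake
#' phenotype and planted ground truth -- under the model described in
#' [synthetic_config()]. Fully determined by the config (including its
#' `rng_seed`): the same config yields bit-identical output, and the
#' caller's RNG stream is left untouched.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `germscreen_sim` with elements
#' \describe{
#'   \item{matrix}{a [metabolome_matrix()] of
#'     `2 x length(timepoints) x n_replicates` samples.}
#'   \item{phenotype}{a `germination_phenotype` tibble with one row per
#'     variety x time point x replicate (germination fraction, fresh and
#'     dry weight).}
#'   \item{truth}{a list with `metabolites` (per-metabolite associated
#'     flag, archetype, effect size, response kinetics, stage-regime
#'     flag),
#'     `samples` (per-sample outlier flag) and `config` (echo).}
#' }
#' @examples
#' sim <- generate_dataset(synthetic_config(n_metabolites = 50,
#'                                          n_associated = 10,
#'                                          rng_seed = 7))
#' sim$matrix
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$rng_seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  tp <- cfg$timepoints
  n_tp <- length(tp)
  n_met <- cfg$n_metabolites
  vfast <- cfg$varieties[1]
  vslow <- cfg$varieties[2]

  met_ids <- sprintf("M%03d", seq_len(n_met))
  class_counts <- allocate_counts(n_met, cfg$class_proportions)
  classes <- sample(rep(names(class_counts), class_counts))

  associated <- rep(FALSE, n_met)
  associated[sample.int(n_met, cfg$n_associated)] <- TRUE

  archetype <- character(n_met)
  n_assoc <- sum(associated)
  if (n_assoc > 0) {
    counts <- allocate_counts(n_assoc, cfg$archetype_mix)
    archetype[associated] <- sample(rep(names(counts), counts))
  }
  n_bg <- n_met - n_assoc
  if (n_bg > 0) {
    counts <- allocate_counts(n_bg, cfg$background_mix)
    archetype[!associated] <- sample(rep(names(counts), counts))
  }

  regime_structured <- rep(FALSE, n_met)
  n_stages <- 1L
  if (!is.null(cfg$stage_regimes)) {
    bg_idx <- which(!associated)
    n_reg <- round(cfg$regime_fraction * length(bg_idx))
    if (n_reg > 0)
      regime_structured[sample(bg_idx, n_reg)] <- TRUE
    n_stages <- length(cfg$stage_regimes) + 1L
  }

  # per-metabolite parameters; both varieties share baseline and amplitude
  base <- rlnorm(n_met, meanlog = log(1e6), sdlog = 1)
  effect <- runif(n_met, cfg$effect_range[1], cfg$effect_range[2])
  resp_mid <- runif(n_met, cfg$response_midpoint_range[1],
                    cfg$response_midpoint_range[2])
  resp_steep <- runif(n_met, cfg$response_steepness_range[1],
                      cfg$response_steepness_range[2])
  # background ramps/bumps share one amplitude scale, milder than planted;
  # saturating kinetics with metabolite-specific half-times spread the
  # dynamics over the whole course, including the early imbibition phase
  bg_effect <- runif(n_met, 0.5, 1.5)
  bg_halftime <- runif(n_met, 3, 24)
  # stage levels for regime-structured metabolites (fast clock)
  stage_mult <- matrix(rlnorm(n_met * n_stages, 0, cfg$regime_level_sdlog),
                       n_met, n_stages)

  stage_of <- function(u) {
    if (is.null(cfg$stage_regimes)) rep(1L, length(u))
    else 1L + rowSums(outer(u, cfg$stage_regimes, `>`))
  }

  mean_at <- function(i, t, lag) {
    g <- germination_curve(t, cfg, lag)
    b <- base[i]
    if (regime_structured[i]) {
      u <- pmax(t - lag, 0)
      return(b * stage_mult[i, stage_of(u)])
    }
    if (associated[i]) {
      u <- pmax(t - lag, 0)
      p <- if (cfg$association_link == "linear") g
           else stats::plogis((u - resp_mid[i]) / resp_steep[i])
      switch(archetype[i],
        "accumulation" = b * (1 + effect[i] * p),
        "consumption" = b * (1 + effect[i] * (1 - p)),
        "accumulation-then-consumption" =
          b * (1 + effect[i] * exp(-((u - resp_mid[i]) / 8)^2)),
        b)
    } else {
      # background dynamics run on the variety's developmental clock
      # (lagged in the slow variety) but do not track the germination
      # curve linearly and share one baseline across varieties
      u <- pmax(t - lag, 0)
      sat <- u / (u + bg_halftime[i])  # imbibition-response kinetics
      switch(archetype[i],
        "flat" = rep(b, length(t)),
        "accumulation" = b * (1 + bg_effect[i] * sat),
        "consumption" = b * (1 + bg_effect[i] * (1 - sat)),
        "accumulation-then-consumption" =
          b * (1 + bg_effect[i] * exp(-((u - 12) / 10)^2)),
        rep(b, length(t)))
    }
  }

  # sample table
  samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                         timepoint_hai = tp,
                         variety = cfg$varieties,
                         KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  samples <- samples[c("variety", "timepoint_hai", "replicate")]
  samples$sample_id <- sprintf("%s-%02dH-%d", samples$variety,
                               samples$timepoint_hai, samples$replicate)

  n_smp <- nrow(samples)
  vals <- matrix(NA_real_, n_smp, n_met,
                 dimnames = list(samples$sample_id, met_ids))
  sigma <- sqrt(log(1 + cfg$noise_cv^2))
  for (i in seq_len(n_met)) {
    for (v in cfg$varieties) {
      lag <- if (v == vslow) cfg$lag_hours else 0
      mu <- mean_at(i, tp, lag)
      rows <- which(samples$variety == v)
      mu_rep <- mu[match(samples$timepoint_hai[rows], tp)]
      vals[rows, i] <- if (cfg$noise_cv == 0) mu_rep
        else if (cfg$noise_model == "lognormal")
          mu_rep * exp(rnorm(length(rows), 0, sigma))
        else pmax(mu_rep + rnorm(length(rows), 0, cfg$noise_cv * mu_rep), 0)
    }
  }

  # outlier replicates: unrelated profile = metabolite labels permuted
  outlier <- rep(FALSE, n_smp)
  if (cfg$n_outlier_replicates > 0) {
    out_rows <- sample.int(n_smp, cfg$n_outlier_replicates)
    for (r in out_rows) vals[r, ] <- vals[r, sample.int(n_met)]
    outlier[out_rows] <- TRUE
  }

  metabolites <- tibble::tibble(
    metabolite_id = met_ids,
    name = met_ids,
    compound_class = classes,
    module_tag = "none")
  mat <- metabolome_matrix(vals, samples, metabolites)

  # phenotype: binomial germination counts and triphasic water uptake
  phen <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      timepoint_hai = tp,
                      variety = cfg$varieties,
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  phen <- phen[c("variety", "timepoint_hai", "replicate")]
  lagv <- ifelse(phen$variety == vslow, cfg$lag_hours, 0)
  g_true <- germination_curve(phen$timepoint_hai, cfg, lagv)
  phen$germination_fraction <- if (cfg$noise_cv == 0) g_true
    else rbinom(nrow(phen), cfg$seeds_per_dish, g_true) / cfg$seeds_per_dish
  dry <- ifelse(phen$variety == vfast, 0.25, 0.27)
  upt <- uptake_curve(phen$timepoint_hai, lagv)
  wnoise <- if (cfg$noise_cv == 0) 1
    else exp(rnorm(nrow(phen), 0, sigma / 5))
  phen$dry_weight <- dry
  # noise multiplies the uptake fraction, keeping fresh >= dry always
  phen$fresh_weight <- dry * (1 + upt * wnoise / 100)
  # binomial counting noise legitimately dips between dense time points,
  # so the monotonicity warning is reserved for user-supplied tables
  phen <- validate_phenotype(phen, check_monotone = cfg$noise_cv == 0)

  truth <- list(
    metabolites = tibble::tibble(
      metabolite_id = met_ids,
      associated = associated,
      archetype = archetype,
      effect_size = ifelse(associated, effect, NA_real_),
      response_midpoint = ifelse(associated, resp_mid, NA_real_),
      response_steepness = ifelse(associated, resp_steep, NA_real_),
      regime_structured = regime_structured,
      compound_class = classes),
    samples = tibble::tibble(sample_id = samples$sample_id,
                             outlier = outlier),
    config = cfg)

  structure(list(matrix = mat, phenotype = phen, truth = truth),
            class = "germscreen_sim")
}

#' @export
print.germscreen_sim <- function(x, ...) {
  cat("<germscreen_sim> seed ", x$truth$config$rng_seed, "\n", sep = "")
  print(x$matrix)
  cat("  planted associated metabolites: ",
      sum(x$truth$metabolites$associated), "\n", sep = "")
  cat("  outlier replicates: ", sum(x$truth$samples$outlier), "\n", sep = "")
  invisible(x)
}

#' Confusion counts of a screen against planted truth
#'
#' Standard 2x2 tally of planted-vs-recovered metabolites, with sensitivity
#' (recall of planted associated metabolites) and precision (fraction of
#' recovered candidates that were planted).
#'
#' @param result a [intersect_screens()] result, or a character vector of
#'   recovered metabolite ids.
#' @param truth the `truth` element of [generate_dataset()] output.
#' @return a list with `tp`, `fp`, `fn`, `tn`, `sensitivity`, `precision`.
#' @export
truth_confusion <- function(result, truth) {
  recovered <- if (inherits(result, "screening_result")) result$candidates
               else as.character(result)
  tm <- truth$metabolites
  if (!all(recovered %in% tm$metabolite_id))
    stop("universe mismatch: recovered set contains metabolites absent ",
         "from the truth record")
  planted <- tm$metabolite_id[tm$associated]
  tp <- length(intersect(recovered, planted))
  fp <- length(setdiff(recovered, planted))
  fn <- length(setdiff(planted, recovered))
  tn <- nrow(tm) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
       precision = if (length(recovered)) tp / length(recovered) else NA_real_)
}
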