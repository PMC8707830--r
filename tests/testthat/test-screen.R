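test_that("pearson_r matches the covariance/sd definition exactly", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1, tolerance = 1e-12)
  expect_equal(pearson_r(1:10, -(1:10)), -1, tolerance = 1e-12)

  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(1, 2, 3, 4, 5, 7)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), brute, tolerance = 1e-12)
  expect_equal(brute, 0.989743318610787, tolerance = 1e-12)

  expect_warning(r <- pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  # pairwise-complete policy
  expect_equal(pearson_r(c(1, 2, 3, NA), c(2, 4, 6, 1)), 1,
               tolerance = 1e-12)
})

test_that("correlation p-values agree with the reference test and behave
           monotonically", {
  set.seed(1)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- cor(x, y)
    expect_equal(correlation_pvalue(r, n),
                 cor.test(x, y)$p.value, tolerance = 1e-12)
  }
  expect_equal(correlation_pvalue(0, 6), 1)
  p1 <- correlation_pvalue(1, 6)
  expect_equal(as.numeric(p1), 0)
  expect_true(attr(p1, "degenerate"))
  expect_error(correlation_pvalue(0.5, 2), "n must be")

  # decreasing in |r| at fixed n, and in n at fixed |r|
  rs <- seq(0.05, 0.95, by = 0.1)
  ps <- vapply(rs, correlation_pvalue, numeric(1), n = 8)
  expect_true(all(diff(ps) < 0))
  ns <- 4:30
  pn <- vapply(ns, function(n) correlation_pvalue(0.6, n), numeric(1))
  expect_true(all(diff(pn) < 0))
})

test_that("analytic and permutation p-values agree where small-sample
           permutation inference permits", {
  # At n = 6 the permutation null conditions on the six observed values
  # (720 discrete permutations), so a case-by-case match with the
  # unconditional t-transform p is not a valid expectation; what must
  # hold is rank agreement between the two p-values and aggregate
  # calibration under the null.
  set.seed(42)
  n <- 6; B <- 2000
  p_ana <- p_perm <- numeric(60)
  for (i in seq_along(p_ana)) {
    x <- rnorm(n); y <- rnorm(n)
    r_obs <- cor(x, y)
    perms <- replicate(B, cor(x, y[sample.int(n)]))
    p_perm[i] <- (1 + sum(abs(perms) >= abs(r_obs) - 1e-12)) / (B + 1)
    p_ana[i] <- correlation_pvalue(r_obs, n)
  }
  expect_gt(cor(p_ana, p_perm, method = "spearman"), 0.95)
  # both are calibrated null p-values: their means sit near 0.5
  expect_lt(abs(mean(p_ana) - 0.5), 3 * sqrt(1 / 12 / 60))
  expect_lt(abs(mean(p_perm) - 0.5), 3 * sqrt(1 / 12 / 60) + 0.02)
})

test_that("cor_screen recovers planted associations and skips degenerates", {
  cfg <- synthetic_config(n_metabolites = 40, n_associated = 10,
                          noise_cv = 0, association_link = "linear",
                          rng_seed = 5)
  sim <- generate_dataset(cfg)
  edges <- cor_screen(sim$matrix, sim$phenotype)
  tru <- sim$truth$metabolites
  planted <- tru$metabolite_id[tru$associated]
  flat <- tru$metabolite_id[!tru$associated & tru$archetype == "flat"]

  for (m in planted) {
    e <- edges[edges$metabolite_id == m, ]
    expect_true(all(e$passes))
    expect_true(all(abs(e$r) > 0.8))
  }
  # exactly-flat metabolites have a constant series and are excluded
  excl <- attr(edges, "excluded")
  expect_true(all(flat %in% excl$metabolite_id))
  expect_match(excl$reason[1], "constant")

  # flat-but-noisy metabolites fail rather than being excluded
  sim2 <- generate_dataset(synthetic_config(n_metabolites = 40,
                                            n_associated = 0,
                                            noise_cv = 0.15, rng_seed = 6))
  e2 <- cor_screen(sim2$matrix, sim2$phenotype)
  tru2 <- sim2$truth$metabolites
  flat2 <- tru2$metabolite_id[tru2$archetype == "flat"]
  fe <- e2[e2$metabolite_id %in% flat2, ]
  expect_lt(mean(fe$passes), 0.05)

  # a missing phenotype time point is a hard error
  ph <- sim$phenotype[sim$phenotype$timepoint_hai != 24, ]
  expect_error(cor_screen(sim$matrix, ph), "missing germination rate")
})

test_that("cv matches its definition and is scale invariant", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(1, 2, 3)), 0.5, tolerance = 1e-12)
  set.seed(2)
  x <- rlnorm(20)
  expect_equal(cv(3.7 * x), cv(x), tolerance = 1e-12)
  expect_warning(v <- cv(c(-2, 1)), "non-positive")
  expect_true(is.na(v))
  expect_error(cv(1), "at least 2")
})

test_that("cv_screen keeps fluctuating metabolites and drops flat ones", {
  # one metabolite doubling every time point, one exactly flat
  tps <- c(0, 3, 6, 9, 12, 24, 36, 48)
  smp <- expand.grid(replicate = 1:2, timepoint_hai = tps,
                     variety = "A", stringsAsFactors = FALSE)
  smp$sample_id <- paste0("s", seq_len(nrow(smp)))
  vals <- cbind(doubling = 2^match(smp$timepoint_hai, tps),
                flat = rep(7, nrow(smp)))
  mat <- metabolome_matrix(vals, smp,
                           data.frame(metabolite_id = colnames(vals)))
  res <- cv_screen(mat)
  expect_true(res$passes[res$metabolite_id == "doubling"])
  expect_equal(res$cv[res$metabolite_id == "doubling"], 1.388764,
               tolerance = 1e-6)
  expect_false(res$passes[res$metabolite_id == "flat"])
  expect_equal(nrow(cv_screen(mat, threshold = Inf)[
    cv_screen(mat, threshold = Inf)$passes, ]), 0)
})

test_that("cv_screen supports the replicate-level basis", {
  sim <- quick_sim(seed = 3)
  m <- cv_screen(sim$matrix, basis = "means")
  r <- cv_screen(sim$matrix, basis = "replicates")
  expect_equal(sort(unique(m$metabolite_id)), sort(unique(r$metabolite_id)))
  # replicate basis folds in replicate noise, so CV is at least comparable
  expect_gt(cor(m$cv, r$cv), 0.9)
})

test_that("dam_screen flags constructed group differences correctly", {
  tps <- c(6, 9, 12, 24, 36, 48)
  smp <- expand.grid(replicate = 1:3, timepoint_hai = c(0, tps),
                     variety = c("fast", "slow"), stringsAsFactors = FALSE)
  smp$sample_id <- paste0("s", seq_len(nrow(smp)))
  set.seed(7)
  jit <- function(x) x * exp(rnorm(length(x), 0, 0.01))
  vals <- cbind(
    same = jit(rep(100, nrow(smp))),
    diff = jit(ifelse(smp$variety == "fast", 1000, 100)))
  mat <- metabolome_matrix(vals, smp,
                           data.frame(metabolite_id = colnames(vals)))
  rec <- dam_screen(mat)
  same <- rec[rec$metabolite_id == "same", ]
  expect_true(all(same$fold_change < 1.1))
  expect_false(any(same$significant))
  d <- rec[rec$metabolite_id == "diff", ]
  # the default pseudo-count (half the smallest positive value) damps
  # the 10x construction somewhat
  expect_true(all(d$fold_change > 5 & d$fold_change < 12))
  expect_true(all(d$significant))
  expect_true(all(d$higher_in == "fast"))
  expect_equal(dam_set(rec), "diff")

  # exactly identical groups: p = 1, fold change 1
  vals0 <- cbind(c0 = rep(5, nrow(smp)))
  m0 <- metabolome_matrix(vals0, smp, data.frame(metabolite_id = "c0"))
  r0 <- dam_screen(m0)
  expect_true(all(r0$raw_p == 1))
  expect_true(all(abs(r0$fold_change - 1) < 1e-12))

  # zero variance with unequal means is degenerate-significant
  vals1 <- cbind(c1 = ifelse(smp$variety == "fast", 10, 1))
  m1 <- metabolome_matrix(vals1, smp, data.frame(metabolite_id = "c1"))
  r1 <- dam_screen(m1)
  expect_true(all(r1$degenerate))
  expect_true(all(r1$raw_p == 0))
  expect_true(all(r1$significant))
})

test_that("dam_screen is symmetric in variety order", {
  sim <- quick_sim(seed = 8)
  a <- dam_screen(sim$matrix, varieties = c("fast", "slow"))
  b <- dam_screen(sim$matrix, varieties = c("slow", "fast"))
  expect_identical(a$significant, b$significant)
  expect_identical(dam_set(a), dam_set(b))
  expect_equal(a$fold_change, b$fold_change, tolerance = 1e-12)
  swapped <- ifelse(a$higher_in == "fast", "slow", "fast")
  expect_identical(b$higher_in[!is.na(b$higher_in)],
                   a$higher_in[!is.na(a$higher_in)])
})

test_that("metabolites with missing replicates are dropped from the test", {
  sim <- quick_sim(seed = 9, n_metabolites = 10, n_associated = 3)
  mat <- sim$matrix
  victim <- colnames(mat$values)[1]
  row6 <- which(mat$samples$variety == "fast" &
                  mat$samples$timepoint_hai == 6)[1]
  mat$values[row6, victim] <- NA
  rec <- dam_screen(mat)
  at6 <- rec[rec$metabolite_id == victim & rec$timepoint_hai == 6, ]
  expect_true(is.na(at6$raw_p))
  expect_false(at6$significant)
})

test_that("BH gating can be switched to raw p-values", {
  sim <- quick_sim(seed = 10)
  adj <- dam_screen(sim$matrix, gate = "adjusted")
  raw <- dam_screen(sim$matrix, gate = "raw")
  expect_true(all(dam_set(adj) %in% dam_set(raw)))
  expect_true(all(adj$adjusted_p >= adj$raw_p - 1e-12, na.rm = TRUE))
})

test_that("intersection respects set algebra and the universe contract", {
  sim <- quick_sim(seed = 11)
  edges <- cor_screen(sim$matrix, sim$phenotype)
  cvr <- cv_screen(sim$matrix)
  dam <- dam_screen(sim$matrix)
  res <- intersect_screens(edges, cvr, dam,
                           annotations = sim$matrix$metabolites)
  expect_true(all(res$candidates %in% res$cor_set))
  expect_true(all(res$candidates %in% res$cv_set))
  expect_true(all(res$candidates %in% res$dam_set))
  expect_equal(sum(res$class_counts), length(res$candidates))

  # intersection across varieties is at most the union result
  res_int <- intersect_screens(edges, cvr, dam,
                               annotations = sim$matrix$metabolites,
                               combine = "intersection")
  expect_true(all(res_int$candidates %in% res$candidates))

  # a filter computed on a different universe is rejected
  sub <- sim$matrix
  keep <- colnames(sub$values)[-1]
  sub2 <- metabolome_matrix(sub$values[, keep], sub$samples,
                            sub$metabolites[-1, ])
  expect_error(intersect_screens(edges, cv_screen(sub2), dam),
               "universe mismatch")
})

test_that("the whole screen is invariant under metabolite reordering and
           sample relabeling", {
  sim <- quick_sim(seed = 12)
  mat <- sim$matrix
  res1 <- intersect_screens(cor_screen(mat, sim$phenotype),
                            cv_screen(mat), dam_screen(mat))

  set.seed(1)
  perm <- sample(ncol(mat$values))
  smp <- mat$samples
  smp$sample_id <- paste0("relabeled_", smp$sample_id)
  mat2 <- metabolome_matrix(mat$values[, perm], smp,
                            mat$metabolites[perm, ])
  res2 <- intersect_screens(cor_screen(mat2, sim$phenotype),
                            cv_screen(mat2), dam_screen(mat2))
  expect_identical(res1$candidates, res2$candidates)
  expect_identical(res1$cor_set, res2$cor_set)
  expect_identical(res1$cv_set, res2$cv_set)
  expect_identical(res1$dam_set, res2$dam_set)
})
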