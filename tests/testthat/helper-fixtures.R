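# shared in-code fixtures for the test suite; everything is generated,
# nothing is read from disk except what a test writes itself

# minimal valid metabolome matrix: v varieties x t timepoints x r reps,
# values drawn reproducibly; metabolite means spread so correlations are
# well-defined
tiny_matrix <- function(n_met = 5, timepoints = c(0, 6, 12, 24),
                        varieties = c("A", "B"), reps = 2, seed = 1,
                        noise = 0.05) {
  set.seed(seed)
  smp <- expand.grid(replicate = seq_len(reps), timepoint_hai = timepoints,
                     variety = varieties, stringsAsFactors = FALSE)
  smp <- smp[c("variety", "timepoint_hai", "replicate")]
  smp$sample_id <- sprintf("%s-%d-%d", smp$variety, smp$timepoint_hai,
                           smp$replicate)
  base <- exp(runif(n_met, log(10), log(1000)))
  slope <- runif(n_met, -0.5, 1)
  vals <- sapply(seq_len(n_met), function(i)
    base[i] * (1 + slope[i] * smp$timepoint_hai / max(timepoints)) *
      exp(rnorm(nrow(smp), 0, noise)))
  colnames(vals) <- sprintf("m%02d", seq_len(n_met))
  metabolome_matrix(vals, smp,
                    data.frame(metabolite_id = colnames(vals)))
}

# phenotype table matching tiny_matrix / a sim design, replicate rows
tiny_phenotype <- function(timepoints = c(0, 6, 12, 24),
                           varieties = c("A", "B"), reps = 2) {
  ph <- expand.grid(replicate = seq_len(reps), timepoint_hai = timepoints,
                    variety = varieties, stringsAsFactors = FALSE)
  ph$germination_fraction <-
    plogis((ph$timepoint_hai - 12) / 4 - (ph$variety == "B") * 1.5)
  ph$dry_weight <- 0.25
  ph$fresh_weight <- 0.25 * (1 + ph$timepoint_hai / 100)
  validate_phenotype(ph)
}

# small fast default sim for tests that just need a coherent dataset
quick_sim <- function(seed = 1, n_metabolites = 60, n_associated = 12,
                      ...) {
  generate_dataset(synthetic_config(n_metabolites = n_metabolites,
                                    n_associated = n_associated,
                                    rng_seed = seed, ...))
}
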