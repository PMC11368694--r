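# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the grid oracle maximizes the likelihood by brute
# force, and the Fisher oracle enumerates hypergeometric tables directly.

# Brute-force single-hit MLE: argmax of the binomial log-likelihood on a
# log-spaced grid of candidate frequencies.
grid_mle_oracle <- function(exp, n_grid = 1e5, f_min = 1e-8, f_max = 1) {
  f <- exp(seq(log(f_min), log(f_max), length.out = n_grid))
  ll <- vapply(f, function(fi) {
    p <- -expm1(-fi * exp$dose)
    sum(ifelse(exp$responding > 0, exp$responding * log(p), 0) -
          (exp$tested - exp$responding) * fi * exp$dose)
  }, numeric(1))
  f[which.max(ll)]
}

# Two-sided Fisher p-value by exhaustive enumeration of 2x2 tables with the
# observed margins: sum the probabilities of all tables no more probable than
# the observed one.
fisher_bruteforce <- function(engrafted_a, total_a, engrafted_b, total_b) {
  k <- engrafted_a + engrafted_b
  support <- max(0, k - total_b):min(k, total_a)
  probs <- dhyper(support, total_a, total_b, k)
  obs <- dhyper(engrafted_a, total_a, total_b, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Small deterministic tidy count table for processing tests.
make_tidy_counts <- function() {
  tibble::tibble(
    barcode   = c("bc1", "bc1", "bc2", "bc2", "bc3", "bc3", "bc4", "bc4"),
    recipient = "r1",
    lineage   = c("B", "B", "B", "B", "M", "M", "N", "N"),
    replicate = rep(c("rep1", "rep2"), 4),
    reads     = c(120L, 0L, 60L, 50L, 50L, 49L, 50L, 50L)
  )
}

# Simulation settings used by the end-to-end recovery checks: generous depth,
# low dispersion and no stochastic dropout, so that every drawn lineage
# survives the 100-read / 2-replicate filter and the realized fate subsets
# equal the latent ones.
recovery_config <- function(seed, n_cells = 25000, subtype_probs = NULL) {
  fp <- default_fate_probabilities()
  if (!is.null(subtype_probs)) fp$custom <- subtype_probs
  barcoding_sim_config(
    library_size = 70000, n_cells = n_cells, transduction_rate = 0.02,
    n_recipients = 2, clone_output_mean = 1000,
    clone_output_dispersion = 0.2, depth_per_sample = 2e6,
    replicate_dropout_rate = 0, fate_probabilities = fp, seed = seed
  )
}

# Run the clonal pipeline (filter -> CPM -> collapse -> detect) on a
# simulated experiment.
run_clonal_pipeline <- function(sim) {
  sim$counts |>
    filter_barcodes() |>
    normalize_cpm() |>
    collapse_replicates() |>
    detect_lineages()
}
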