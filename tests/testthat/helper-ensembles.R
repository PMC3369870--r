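# Shared, lazily computed ensembles for the heavier checks.  The study
# conditions mirror the headline experiments: haploid sample length M = 100,
# 400 realizations per curve point, N = 100 diploid individuals (M = 200
# alleles) for the classical-drift calibration.
.ens_cache <- new.env()

cached <- function(name, fn) {
  if (is.null(.ens_cache[[name]])) .ens_cache[[name]] <- fn()
  .ens_cache[[name]]
}

acc_p0_grid <- seq(0.1, 0.9, by = 0.1)
acc_p0_inner <- seq(0.2, 0.8, by = 0.1)

acc_gm_ensemble <- function() cached("gm_ens", function() {
  run_ensemble(canonical_machine("golden_mean", p = 0.5), M = 100,
               cfg = no_innovation(), n_realizations = 400,
               record = "full", seed = 201206)
})

# structural drift of the (biased) coin across initial biases
acc_bc_curve <- function() cached("bc_curve", function() {
  lapply(seq_along(acc_p0_grid), function(i) {
    run_ensemble(canonical_machine("biased_coin", p = acc_p0_grid[i]),
                 M = 100, cfg = no_innovation(), n_realizations = 400,
                 record = "minimal", seed = 7000 + i)
  })
})

acc_gm_curve <- function() cached("gm_curve", function() {
  lapply(seq_along(acc_p0_inner), function(i) {
    run_ensemble(canonical_machine("golden_mean", p = acc_p0_inner[i]),
                 M = 100, cfg = no_innovation(), n_realizations = 400,
                 record = "minimal", seed = 8000 + i)
  })
})

acc_even_curve <- function() cached("even_curve", function() {
  lapply(seq_along(acc_p0_inner), function(i) {
    run_ensemble(canonical_machine("even", p = acc_p0_inner[i]),
                 M = 100, cfg = no_innovation(), n_realizations = 400,
                 record = "minimal", seed = 9000 + i)
  })
})

# Monte Carlo memoryless drift at the same haploid size, absorbing at either
# boundary (time to stasis)
acc_mc_stasis_curve <- function() cached("mc_stasis", function() {
  set.seed(6001)
  lapply(acc_p0_grid, function(p) mc_ensemble(p, M = 100, n = 400))
})

acc_innovation_ensemble <- function() cached("innov_ens", function() {
  run_ensemble(canonical_machine("golden_mean", p = 0.5), M = 100,
               cfg = psv_config(innovation_rate = 1), n_realizations = 400,
               record = "minimal", seed = 424242)
})

mean_se <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
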