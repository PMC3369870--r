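test_that("model scores penalize parameters as configured", {
  # deterministic machine on its own output: ln L = 1, score is pure penalty
  fx <- canonical_machine("fixed_coin", symbol = "T")
  s <- rep("T", 50)
  k <- nrow(transitions(fx))  # one stored transition = one parameter
  expect_equal(model_score(fx, s, "AIC"), 2 * k)
  expect_equal(model_score(fx, s, "AICc"),
               2 * k + 2 * k * (k + 1) / (50 - k - 1))

  # fair coin vs fixed coin on a homogeneous sample: the fixed coin wins
  fc <- canonical_machine("fair_coin")
  fxH <- machine(data.frame(from = "A", symbol = "H", to = "A", p = 1),
                 alphabet = c("H", "T"))
  h4 <- rep("H", 40)
  expect_lt(model_score(fxH, h4, "AICc"), model_score(fc, h4, "AICc"))

  # golden mean: k = 3 stored transitions; AICc penalty term at n = 100
  gm <- canonical_machine("golden_mean", p = 0.5)
  set.seed(1)
  sg <- generate_population(gm, 100)
  k <- nrow(transitions(reestimate(gm, sg)))
  expect_equal(model_score(reestimate(gm, sg), sg, "AICc") -
                 model_score(reestimate(gm, sg), sg, "AIC"),
               2 * k * (k + 1) / (100 - k - 1), tolerance = 1e-10)

  # AICc falls back to AIC with a warning when n <= k + 1
  expect_warning(sc <- model_score(gm, c("0", "1", "0"), "AICc"), "AICc")
})

test_that("innovation clones states only when it raises the likelihood", {
  cfg <- psv_config(noise_sigma = 0.05)
  # single incoming edge: cloning cannot split, machine returned unchanged
  fx <- canonical_machine("fixed_coin", symbol = "T")
  out <- innovate(fx, rep("T", 30), cfg)
  expect_false(attr(out, "innovation_accepted"))
  expect_length(out$states, 1)

  # an IID coin confronted with a strongly period-2 sample: an accepted
  # clone captures the alternation, and re-estimation then recovers the
  # alternating machine
  bc01 <- machine(data.frame(from = "A", symbol = c("0", "1"), to = "A",
                             p = c(0.5, 0.5)), alphabet = c("0", "1"))
  s <- rep(c("0", "1"), 60)
  set.seed(2)
  accepted <- NULL
  for (i in 1:60) {
    cand <- innovate(bc01, s, cfg)
    if (attr(cand, "innovation_accepted")) { accepted <- cand; break }
  }
  expect_false(is.null(accepted))
  expect_length(accepted$states, 2)
  expect_gt(parse_population(accepted, s)$log_likelihood,
            parse_population(bc01, s)$log_likelihood)
  expect_equal(signature_class(canonicalize(reestimate(accepted, s))), "AP")

  # acceptance never lowers the sample likelihood (MAP with uniform prior)
  gm <- canonical_machine("golden_mean", p = 0.5)
  set.seed(3)
  for (i in 1:25) {
    sg <- generate_population(gm, 80)
    cand <- innovate(gm, sg, cfg)
    expect_gte(parse_population(cand, sg)$log_likelihood,
               parse_population(gm, sg)$log_likelihood)
    expect_silent(validate_machine(cand))
  }
})

test_that("structural loss merges only when the penalized score favors it", {
  cfg <- psv_config(innovation_rate = 0)
  # rare-branch golden mean with a sample lacking the rare symbol: the
  # merged one-state machine (fitting perfectly with fewer parameters) wins
  gm_rare <- canonical_machine("golden_mean", p = 0.005)
  s0 <- rep("0", 100)
  out <- try_loss(gm_rare, s0, cfg)
  expect_length(out$states, 1)

  # no transition below threshold: unchanged
  gm <- canonical_machine("golden_mean", p = 0.5)
  s <- strsplit("01010010010", "")[[1]]
  expect_identical(try_loss(gm, s, cfg), gm)

  # merging the alternating machine is rejected while both symbols occur:
  # the likelihood collapse outweighs any parameter saving
  ap <- canonical_machine("alternating")
  s2 <- rep(c("0", "1"), 50)
  merged <- reestimate(canonicalize(merge_states(ap, "A", "B")), s2)
  expect_gt(model_score(merged, s2, "AICc"), model_score(ap, s2, "AICc"))
})

test_that("merging resolves unifilarity conflicts recursively", {
  # merging the two states of the golden mean yields a single-state coin
  gm <- canonical_machine("golden_mean", p = 0.4)
  m <- canonicalize(merge_states(gm, "A", "B"))
  expect_length(m$states, 1)
  expect_equal(signature_class(m), "BC")
  expect_silent(validate_machine(m))
})

test_that("drift terminates in stasis and records a consistent trajectory", {
  # machine already at stasis: absorbed at generation 0
  fx <- canonical_machine("fixed_coin")
  tr <- run_drift(fx, M = 50, cfg = no_innovation(), seed = 1)
  expect_equal(tr$stasis_time, 0L)
  expect_equal(tr$terminal_status, "stasis")

  gm <- canonical_machine("golden_mean", p = 0.5)
  tr <- run_drift(gm, M = 100, cfg = no_innovation(), seed = 7)
  expect_equal(tr$terminal_status, "stasis")
  r <- tr$records
  expect_equal(r$generation, 0:tr$stasis_time)
  expect_equal(r$h_mu[nrow(r)], 0)
  expect_true(all(r$h_mu[-nrow(r)] > 0))
  expect_equal(allelic_entropy(tr$stasis_machine), 0)
  # signature changes exactly when a jump event is recorded
  jumps <- grepl("subspace_jump", r$event)
  expect_equal(which(r$signature[-1] != r$signature[-nrow(r)]) + 1,
               which(jumps))

  # golden-mean drift without innovation terminates as fixed coin or
  # alternating and never exceeds two states
  set.seed(77)
  cls <- replicate(12, {
    t2 <- run_drift(gm, M = 100, cfg = no_innovation(), record = "minimal")
    expect_lte(t2$max_states, 2)
    signature_class(t2$stasis_machine)
  })
  expect_true(all(cls %in% c("FC", "AP")))
})

test_that("stasis is an absorbing fixed point of the drift map", {
  gm <- canonical_machine("golden_mean", p = 0.5)
  set.seed(13)
  for (i in 1:5) {
    tr <- run_drift(gm, M = 100, cfg = no_innovation(), record = "minimal")
    m <- tr$stasis_machine
    for (g in 1:20) {
      s <- generate_population(m, 100)
      m2 <- try_loss(reestimate(m, s), s, no_innovation())
      expect_true(machine_equal(m2, m))
      m <- m2
    }
  }
})

test_that("ensembles are bitwise reproducible under a master seed", {
  gm <- canonical_machine("golden_mean", p = 0.5)
  cfg <- psv_config(innovation_rate = 1)
  a <- run_ensemble(gm, 100, cfg, n_realizations = 3, record = "full",
                    seed = 99)
  b <- run_ensemble(gm, 100, cfg, n_realizations = 3, record = "full",
                    seed = 99)
  expect_identical(lapply(a, unclass), lapply(b, unclass))
})

test_that("coin-subspace drift follows the one-step binomial law", {
  # one structural-drift generation from a biased coin is binomial
  # resampling of the bias: compare the one-step count histogram at M = 20
  # against the exact pmf
  bc <- canonical_machine("biased_coin", p = 0.35)
  M <- 20
  set.seed(101)
  draws <- replicate(2e4, {
    s <- generate_population(bc, M)
    sum(s == "H")
  })
  pmf <- binomial_transition_pmf(0.35 * M, M)
  obs <- tabulate(draws + 1, nbins = M + 1)
  keep <- pmf > 1e-8
  # tail bins have tiny expectation; the chi-square small-count warning is
  # immaterial for this comparison
  chi <- suppressWarnings(
    stats::chisq.test(obs[keep], p = pmf[keep] / sum(pmf[keep])))
  expect_gt(chi$p.value, 1e-4)
})

test_that("machines along random drift trajectories stay valid", {
  set.seed(404)
  gm <- canonical_machine("golden_mean", p = 0.5)
  for (i in 1:3) {
    tr <- run_drift(gm, M = 60, cfg = psv_config(innovation_rate = 1),
                    record = "full")
    expect_true(all(tr$records$h_mu >= 0))
    expect_true(all(tr$records$n_states >= 1))
    expect_silent(validate_machine(tr$terminal_machine))
  }
})
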