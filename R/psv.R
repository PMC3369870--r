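#' PSV drift configuration
#'
#' Settings for the pseudo-sampling-variable structural drift algorithm,
#' which replaces full epsilon-machine reconstruction with explicit
#' structural-innovation (state cloning) and structural-loss (state merging)
#' proposals.
#'
#' @param noise_sigma standard deviation of the Gaussian perturbation applied
#'   to a cloned state's outgoing probabilities (default `0.05`).
#' @param merge_threshold transition probability below which the loss test is
#'   triggered (default `0.05`).  The threshold only decides when merges are
#'   *tested*; acceptance is decided by the penalized likelihood, so it needs
#'   only to be small enough to skip pointless tests.
#' @param innovation_rate cloning proposals per generation (`0` disables
#'   innovation).
#' @param aic_correction `"AICc"` (default; finite-sample corrected) or
#'   `"AIC"`.
#' @param max_generations safety cap on drift length (default `1e6`).
#' @param prob_floor clipping floor applied after noise, before
#'   renormalization, so the noise step alone never deletes an edge
#'   (default `1e-6`).
#' @param stasis_tol entropy tolerance for the stasis test (default `1e-12`).
#' @param rng_seed optional seed applied by [run_drift()].
#' @return list of class `psv_config`.
#' @export
psv_config <- function(noise_sigma = 0.05, merge_threshold = 0.05,
                       innovation_rate = 1, aic_correction = c("AICc", "AIC"),
                       max_generations = 1e6, prob_floor = 1e-6,
                       stasis_tol = 1e-12, rng_seed = NULL) {
  stopifnot(noise_sigma > 0, merge_threshold > 0, merge_threshold < 1,
            innovation_rate >= 0, prob_floor > 0)
  structure(list(noise_sigma = noise_sigma,
                 merge_threshold = merge_threshold,
                 innovation_rate = as.integer(innovation_rate),
                 aic_correction = match.arg(aic_correction),
                 max_generations = max_generations,
                 prob_floor = prob_floor,
                 stasis_tol = stasis_tol,
                 rng_seed = rng_seed),
            class = "psv_config")
}

#' Penalized model score (AIC / AICc)
#'
#' Scores a machine against a sample by the Akaike Information Criterion,
#' `AIC = 2k - 2 ln L`, with the parameter count `k` taken as the number of
#' stored transitions (each stored transition probability is a model
#' parameter).  `AICc` adds the finite-sample correction
#' `2k(k+1)/(n-k-1)` with `n` the sample length, falling back to plain AIC
#' with a warning when `n <= k + 1`.  Lower is better.  The parse
#' log-likelihood is base 2; the conversion to natural log is internal.
#'
#' @param m a [machine].
#' @param symbols population sample.
#' @param criterion `"AICc"` (default) or `"AIC"`.
#' @return penalized score (scalar; `Inf` for an unparseable sample).
#' @export
model_score <- function(m, symbols, criterion = c("AICc", "AIC")) {
  criterion <- match.arg(criterion)
  ll2 <- parse_population(m, symbols, start = "best")$log_likelihood
  if (!is.finite(ll2)) return(Inf)
  k <- n_edges(m)
  n <- length(symbols_to_int(m, symbols))
  aic <- 2 * k - 2 * (ll2 * log(2))
  if (criterion == "AIC") return(aic)
  if (n <= k + 1) {
    warning("AICc undefined for n <= k + 1; falling back to AIC")
    return(aic)
  }
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Structural innovation by state cloning
#'
#' Proposes a larger machine: a uniformly chosen causal state is cloned (the
#' clone copies its outgoing transitions), each transition incoming to the
#' original is independently rerouted to the clone with probability 1/2
#' (resampled until at least one is rerouted and one kept), and Gaussian
#' noise is added to the clone's outgoing probabilities (clipped to
#' `[prob_floor, 1]` and renormalized).  Unifilarity is preserved by
#' construction.  The proposal is retained only if its best-start sample
#' log-likelihood strictly exceeds the incumbent's (uniform model prior, so
#' the MAP comparison reduces to likelihood); ties keep the smaller
#' incumbent.  States with fewer than two incoming transitions cannot split
#' their incoming edges, in which case `m` is returned unchanged.
#'
#' @param m a [machine].
#' @param symbols population sample (parseable by `m`).
#' @param cfg a [psv_config()].
#' @return a [machine]: the accepted proposal or `m`; the attribute
#'   `"innovation_accepted"` records which.
#' @export
innovate <- function(m, symbols, cfg = psv_config()) {
  si <- symbols_to_int(m, symbols)
  res <- innovate_impl(m, si, cfg)
  structure(res$machine, innovation_accepted = res$accepted)
}

innovate_impl <- function(m, si, cfg) {
  S <- n_states(m)
  pick <- sample.int(S, 1)
  incoming <- which(m$target == pick, arr.ind = TRUE)
  if (nrow(incoming) < 2) {
    return(list(machine = m, accepted = FALSE))
  }
  clone <- S + 1L
  target <- rbind(m$target, m$target[pick, ])
  prob <- rbind(m$prob, m$prob[pick, ])
  repeat {
    flip <- stats::runif(nrow(incoming)) < 0.5
    if (any(flip) && !all(flip)) break
  }
  target[incoming[flip, , drop = FALSE]] <- clone
  pos <- which(target[clone, ] > 0)
  pr <- prob[clone, pos] + stats::rnorm(length(pos), 0, cfg$noise_sigma)
  pr <- pmin(pmax(pr, cfg$prob_floor), 1)
  prob[clone, pos] <- pr / sum(pr)
  states <- c(m$states, clone_name(m$states, m$states[pick]))
  m2 <- new_machine(states, m$alphabet, target, prob, notes = m$notes)
  ll1 <- best_loglik(m, si)
  ll2 <- best_loglik(m2, si)
  if (ll2 > ll1) list(machine = m2, accepted = TRUE)
  else list(machine = m, accepted = FALSE)
}

clone_name <- function(states, base) {
  cand <- paste0(base, "'")
  while (cand %in% states) cand <- paste0(cand, "'")
  cand
}

best_loglik <- function(m, si) {
  best <- -Inf
  for (s in seq_len(n_states(m))) {
    ll <- cpp_parse(m$target, m$prob, si, s)$log_likelihood
    if (ll > best) best <- ll
  }
  best
}

#' Merge two causal states of a machine
#'
#' Forms the quotient machine in which `i` and `j` are identified.
#' Unifilarity conflicts (both members emitting the same symbol to different
#' targets) are resolved by recursively merging the conflicting targets,
#' mirroring classical automaton state merging.  Per-symbol probabilities of
#' merged members are summed and the rows renormalized.
#'
#' @param m a [machine].
#' @param i,j state identifiers (or indices) to merge.
#' @return a [machine].
#' @export
merge_states <- function(m, i, j) {
  S <- n_states(m)
  ii <- if (is.character(i)) match(i, m$states) else as.integer(i)
  jj <- if (is.character(j)) match(j, m$states) else as.integer(j)
  stopifnot(!is.na(ii), !is.na(jj), ii != jj)
  parent <- seq_len(S)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  union2(ii, jj)
  K <- length(m$alphabet)
  repeat {
    changed <- FALSE
    roots <- unique(vapply(seq_len(S), find, integer(1)))
    for (r in roots) {
      members <- which(vapply(seq_len(S), find, integer(1)) == r)
      for (a in seq_len(K)) {
        tg <- m$target[members, a]
        tg <- unique(vapply(tg[tg > 0], find, integer(1)))
        if (length(tg) > 1) {
          for (x in tg[-1]) union2(tg[1], x)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  root_of <- vapply(seq_len(S), find, integer(1))
  roots <- sort(unique(root_of))
  nb <- length(roots)
  grp <- match(root_of, roots)
  tgt <- matrix(0L, nb, K)
  prb <- matrix(0, nb, K)
  for (b in seq_len(nb)) {
    members <- which(grp == b)
    for (a in seq_len(K)) {
      tg <- m$target[members, a]
      pv <- m$prob[members, a]
      if (any(tg > 0)) {
        tgt[b, a] <- grp[tg[tg > 0][1]]
        prb[b, a] <- sum(pv)
      }
    }
    prb[b, ] <- prb[b, ] / sum(prb[b, ])
  }
  labels <- vapply(seq_len(nb), function(b)
    m$states[which(grp == b)[1]], character(1))
  new_machine(labels, m$alphabet, tgt, prb, notes = m$notes)
}

#' Structural loss by AICc-penalized state merging
#'
#' If any transition probability falls below `cfg$merge_threshold`, every
#' unordered pair of states is merged in turn; each candidate is
#' canonicalized, re-fit to the sample by [reestimate()], and scored with
#' [model_score()].  The minimizer among the candidates and the incumbent is
#' returned; score ties favor the smaller machine (fewer states, then fewer
#' edges).  Without a triggering transition `m` is returned unchanged.
#'
#' @param m a [machine] (typically already re-estimated from `symbols`).
#' @param symbols population sample.
#' @param cfg a [psv_config()].
#' @return a [machine].
#' @export
try_loss <- function(m, symbols, cfg = psv_config()) {
  if (!any(m$prob > 0 & m$prob < cfg$merge_threshold)) return(m)
  S <- n_states(m)
  if (S < 2) return(m)
  crit <- cfg$aic_correction
  best <- m
  best_sc <- model_score(m, symbols, crit)
  best_size <- c(S, n_edges(m))
  for (i in seq_len(S - 1)) {
    for (j in seq(i + 1, S)) {
      cand <- tryCatch({
        mm <- canonicalize(merge_states(m, i, j))
        reestimate(mm, symbols)
      }, error = function(e) NULL)
      if (is.null(cand)) next
      sc <- tryCatch(model_score(cand, symbols, crit), error = function(e) Inf)
      if (!is.finite(sc)) next
      size <- c(n_states(cand), n_edges(cand))
      if (sc < best_sc - 1e-12 ||
          (abs(sc - best_sc) <= 1e-12 &&
           (size[1] < best_size[1] ||
            (size[1] == best_size[1] && size[2] < best_size[2])))) {
        best <- cand
        best_sc <- sc
        best_size <- size
      }
    }
  }
  best
}
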