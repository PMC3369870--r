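#' Fisher-Wright binomial transition distribution
#'
#' The probability of `j` copies of an allele among `M` total alleles in the
#' offspring generation given `i` copies in the parent generation:
#' `Binomial(M, i/M)` over `j = 0..M`.  The absorbing boundaries `i = 0` and
#' `i = M` give point masses.
#'
#' @param i current allele count, `0 <= i <= M`.
#' @param M total number of alleles in the population (`2N` diploid, `N`
#'   haploid).
#' @return named numeric vector of length `M + 1` over `j = 0..M`.
#' @export
binomial_transition_pmf <- function(i, M) {
  stopifnot(length(i) == 1, i >= 0, i <= M)
  stats::setNames(stats::dbinom(0:M, M, i / M), 0:M)
}

#' Moments of the one-generation allele-frequency change
#'
#' Under neutral binomial resampling the frequency change has mean zero
#' (drift is a martingale) and variance `p (1 - p) / M`.
#'
#' @param p current allele frequency.
#' @param M total number of alleles.
#' @return named numeric vector `c(mean, variance)`.
#' @export
delta_p_moments <- function(p, M) {
  c(mean = 0, variance = p * (1 - p) / M)
}

#' Monte Carlo simulation of memoryless genetic drift
#'
#' Repeated binomial sampling with maximum-likelihood re-estimation: each
#' generation draws `M` alleles with the current frequency, then sets the
#' frequency to the realized count over `M`, until fixation (`p = 1`) or
#' deletion (`p = 0`).
#'
#' @param p0 initial allele frequency.
#' @param M total number of alleles per generation.
#' @param max_generations safety cap (default `1e6`); if reached the outcome
#'   is flagged `"unabsorbed"`.
#' @param keep_trajectory record the per-generation frequencies.
#' @return list with `generations`, `absorbed_at`
#'   (`"fixation"`/`"deletion"`/`"unabsorbed"`), and optionally `trajectory`.
#' @examples
#' set.seed(1)
#' mc_drift(0.5, 100)$generations
#' @export
mc_drift <- function(p0, M, max_generations = 1e6, keep_trajectory = FALSE) {
  stopifnot(p0 >= 0, p0 <= 1, M >= 1)
  p <- p0
  traj <- if (keep_trajectory) p0 else NULL
  gen <- 0
  while (p > 0 && p < 1 && gen < max_generations) {
    p <- stats::rbinom(1, M, p) / M
    gen <- gen + 1
    if (keep_trajectory) traj <- c(traj, p)
  }
  list(generations = gen,
       absorbed_at = if (p == 1) "fixation" else if (p == 0) "deletion"
                     else "unabsorbed",
       trajectory = traj)
}

#' Ensemble of Monte Carlo drift realizations
#'
#' Vectorized across realizations: all chains advance together until
#' absorbed.
#'
#' @inheritParams mc_drift
#' @param n number of realizations.
#' @return data frame with columns `outcome` and `generations`.
#' @export
mc_ensemble <- function(p0, M, n, max_generations = 1e6) {
  p <- rep(p0, n)
  gens <- integer(n)
  active <- p > 0 & p < 1
  g <- 0
  while (any(active) && g < max_generations) {
    g <- g + 1
    idx <- which(active)
    p[idx] <- stats::rbinom(length(idx), M, p[idx]) / M
    done <- idx[p[idx] == 0 | p[idx] == 1]
    gens[done] <- g
    active[done] <- FALSE
  }
  gens[active] <- g
  data.frame(outcome = ifelse(p == 1, "fixation",
                              ifelse(p == 0, "deletion", "unabsorbed")),
             generations = gens)
}

#' Kimura-Ohta conditional mean absorption times
#'
#' Diffusion-theory predictions for the neutral Fisher-Wright model: the mean
#' number of generations until fixation, conditioned on fixation
#' (`kimura_t1`), or until deletion, conditioned on deletion (`kimura_t0`),
#' for initial frequency `p`:
#' \deqn{\bar t_1(p) = -\frac{1}{p}\, 4 N_e (1 - p) \ln(1 - p),}
#' \deqn{\bar t_0(p) = -4 N_e \frac{p}{1 - p} \ln p.}
#' In the rare-allele limit \eqn{p \to 0}, \eqn{\bar t_1 \to 4 N_e}: an
#' initially rare mutant that escapes deletion spreads through the whole
#' population in about `4 Ne` generations.
#'
#' @param p initial allele frequency in `(0, 1)` (vectorized).
#' @param Ne effective population size (diploid individuals; the total allele
#'   count is `2 Ne`).
#' @return mean absorption time in generations.
#' @export
kimura_t1 <- function(p, Ne) {
  stopifnot(all(p > 0), all(p < 1))
  -(1 / p) * 4 * Ne * (1 - p) * log(1 - p)
}

#' @rdname kimura_t1
#' @export
kimura_t0 <- function(p, Ne) {
  stopifnot(all(p > 0), all(p < 1))
  -4 * Ne * (p / (1 - p)) * log(p)
}

#' Exact absorption times of the finite Fisher-Wright chain
#'
#' Solves the discrete binomial-resampling Markov chain by linear algebra:
#' unconditional mean absorption times, fixation probabilities, and the
#' fixation-/deletion-conditioned mean times from every interior allele count
#' `i = 1..M-1`.  Serves as the finite-`M` ground truth against which the
#' Kimura-Ohta diffusion formulas are an approximation.
#'
#' @param M total number of alleles.
#' @return list with vectors (indexed by `i = 1..M-1`): `p` (= `i/M`), `u`
#'   (fixation probability), `t_abs` (unconditional), `t_fix`
#'   (fixation-conditioned), `t_del` (deletion-conditioned).
#' @export
wf_absorption_times <- function(M) {
  i <- seq_len(M - 1)
  Q <- t(vapply(i, function(ii) stats::dbinom(i, M, ii / M), numeric(M - 1)))
  rfix <- vapply(i, function(ii) stats::dbinom(M, M, ii / M), numeric(1))
  A <- diag(M - 1) - Q
  u <- solve(A, rfix)
  t_abs <- solve(A, rep(1, M - 1))
  t_fix <- solve(A, u) / u
  t_del <- solve(A, 1 - u) / (1 - u)
  list(p = i / M, u = u, t_abs = t_abs, t_fix = t_fix, t_del = t_del)
}
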