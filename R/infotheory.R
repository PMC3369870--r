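#' Exact word distribution of a machine
#'
#' The probability of every length-`L` allele word under the stationary
#' process: `Pr(w) = sum_s pi(s) Pr(w | start s)`, computed exactly along the
#' unifilar paths of the recurrent component.  Words of probability zero are
#' omitted.
#'
#' @param m a [machine].
#' @param L word length (`|A|^L` is guarded at `1e6`).
#' @return named numeric vector of word probabilities summing to one.
#' @examples
#' word_distribution(canonical_machine("alternating"), 2)
#' @export
word_distribution <- function(m, L) {
  stopifnot(L >= 1)
  K <- length(m$alphabet)
  if (K^L > 1e6) stop("|A|^L exceeds enumeration guard of 1e6")
  pi <- stationary_distribution(m)
  rec <- which(pi > 0)
  n <- length(rec)
  idx <- match(seq_len(n_states(m)), rec)
  # per-symbol state-to-state matrices on the recurrent component
  Ta <- lapply(seq_len(K), function(a) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      t2 <- m$target[rec[i], a]
      if (t2 > 0) M[i, idx[t2]] <- m$prob[rec[i], a]
    }
    M
  })
  W <- matrix(pi[rec], 1, n)
  words <- ""
  for (l in seq_len(L)) {
    Wn <- vector("list", K)
    wn <- vector("list", K)
    for (a in seq_len(K)) {
      Wn[[a]] <- W %*% Ta[[a]]
      wn[[a]] <- paste0(words, m$alphabet[a])
    }
    W <- do.call(rbind, Wn)
    words <- unlist(wn)
    pos <- rowSums(W) > 0
    W <- W[pos, , drop = FALSE]
    words <- words[pos]
  }
  stats::setNames(rowSums(W), words)
}

#' Population diversity (block entropy)
#'
#' The Shannon entropy `H(L)` of the length-`L` word distribution, in bits.
#' `H(L)` is nondecreasing and subadditive in `L`; its growth rate converges
#' to the allelic entropy.
#'
#' @inheritParams word_distribution
#' @return entropy in bits.
#' @export
population_diversity <- function(m, L) {
  p <- word_distribution(m, L)
  -sum(p * log2(p))
}

#' Allelic entropy (entropy rate)
#'
#' The per-allele entropy rate of the sampling process in bits per allele,
#' computed in closed form from the machine:
#' `h = -sum_s pi(s) sum_(a,s') T^a(s,s') log2 T^a(s,s')`,
#' restricted to the recurrent component.  It is zero exactly when no
#' recurrent state branches, i.e. at structural stasis.
#'
#' @param m a [machine].
#' @return entropy rate in bits per allele.
#' @examples
#' allelic_entropy(canonical_machine("golden_mean", p = 0.5))  # 2/3
#' @export
allelic_entropy <- function(m) {
  machine_summary(m)$h_mu
}

#' Allelic complexity (statistical complexity)
#'
#' The Shannon entropy of the stationary causal-state distribution, in bits:
#' the memory required to track the machine's internal state.
#'
#' @param m a [machine].
#' @return complexity in bits.
#' @examples
#' allelic_complexity(canonical_machine("alternating"))  # 1 bit
#' @export
allelic_complexity <- function(m) {
  machine_summary(m)$C_mu
}

#' Test for structural stasis
#'
#' Structural stasis — the generalization of fixation, deletion and
#' periodicity — occurs when the allelic entropy vanishes.  With
#' integer-count re-estimation, stasis machines carry probability-1 edges
#' only, so the entropy is exactly zero and the tolerance merely guards
#' floating-point dust.
#'
#' @param m a [machine].
#' @param tol entropy threshold in bits per allele (default `1e-12`).
#' @return logical.
#' @export
is_stasis <- function(m, tol = 1e-12) {
  allelic_entropy(m) < tol
}

#' Combined information summary of a machine
#'
#' @param m a [machine].
#' @param tol stasis tolerance passed to [is_stasis()].
#' @return list with `h_mu` (bits/allele), `C_mu` (bits), `is_stasis`.
#' @export
info_summary <- function(m, tol = 1e-12) {
  s <- machine_summary(m)
  list(h_mu = s$h_mu, C_mu = s$C_mu, is_stasis = s$h_mu < tol)
}
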