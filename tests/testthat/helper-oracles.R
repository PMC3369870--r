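# Independent oracles used across the suite.

# stationary distribution by power iteration with Cesaro averaging (so
# periodic chains converge too); independent of the package's linear solve
power_iterate_stationary <- function(m, burnin = 500, iters = 4000) {
  S <- length(m$states)
  Tss <- matrix(0, S, S)
  tr <- transitions(m)
  for (i in seq_len(nrow(tr))) {
    a <- match(tr$from[i], m$states)
    b <- match(tr$to[i], m$states)
    Tss[a, b] <- Tss[a, b] + tr$p[i]
  }
  v <- rep(1 / S, S)
  for (i in seq_len(burnin)) v <- as.vector(v %*% Tss)
  acc <- numeric(S)
  for (i in seq_len(iters)) {
    v <- as.vector(v %*% Tss)
    acc <- acc + v
  }
  stats::setNames(acc / sum(acc), m$states)
}

# machines considered equal up to bookkeeping (transient flags, notes)
machine_equal <- function(a, b) {
  identical(a$states, b$states) && identical(a$alphabet, b$alphabet) &&
    identical(a$target, b$target) && isTRUE(all.equal(a$prob, b$prob))
}

# a small pool of random valid unifilar machines for property tests
# (resampled until the recurrent part is a single terminal component, the
# precondition of the stationary-distribution operations)
random_machine <- function(n_states = sample(1:4, 1), n_symbols = 2) {
  repeat {
    states <- LETTERS[seq_len(n_states)]
    alphabet <- as.character(seq_len(n_symbols) - 1)
    rows <- list()
    for (s in states) {
      syms <- sample(alphabet, sample(seq_len(n_symbols), 1))
      p <- as.vector(stats::rgamma(length(syms), 1)) + 0.05
      p <- p / sum(p)
      rows[[s]] <- data.frame(from = s, symbol = syms,
                              to = sample(states, length(syms), replace = TRUE),
                              p = p)
    }
    m <- machine(do.call(rbind, rows), states = states, alphabet = alphabet)
    ok <- tryCatch({stationary_distribution(m); TRUE},
                   error = function(e) FALSE)
    if (ok) return(m)
  }
}

no_innovation <- function(...) psv_config(innovation_rate = 0, ...)

machine_summary_safe <- function(m) structdrift:::machine_summary(m)
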