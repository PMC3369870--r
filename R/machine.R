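#' Unifilar probabilistic finite-state machines
#'
#' A `machine` is the package's representation of an epsilon-machine: a
#' unifilar (per-state, per-symbol deterministic) probabilistic finite-state
#' generator over a finite allele alphabet.  Internally the transition
#' structure is stored as two `|S| x |A|` matrices: `target[s, a]` gives the
#' successor state index (0 when the transition is absent) and `prob[s, a]`
#' the corresponding emission probability.  Unifilarity is therefore enforced
#' by construction: a (state, symbol) pair indexes at most one transition.
#'
#' @param transitions data frame with columns `from`, `symbol`, `to`, `p`.
#'   Zero-probability rows are dropped (zero edges are deleted, not stored).
#' @param states character vector of state identifiers; defaults to the states
#'   appearing in `transitions`.
#' @param alphabet character vector of symbols; defaults to the symbols
#'   appearing in `transitions`.
#' @param notes free-form provenance string.
#' @return an object of class `machine`.
#' @examples
#' m <- machine(data.frame(
#'   from = c("A", "A", "B"), symbol = c("0", "1", "0"),
#'   to = c("A", "B", "A"), p = c(0.5, 0.5, 1)))
#' allelic_entropy(m)
#' @export
machine <- function(transitions, states = NULL, alphabet = NULL, notes = "") {
  stopifnot(is.data.frame(transitions),
            all(c("from", "symbol", "to", "p") %in% names(transitions)))
  tr <- transitions
  tr$from <- as.character(tr$from)
  tr$symbol <- as.character(tr$symbol)
  tr$to <- as.character(tr$to)
  tr <- tr[tr$p > 0, , drop = FALSE]
  if (is.null(states)) states <- sort(unique(c(tr$from, tr$to)))
  if (is.null(alphabet)) alphabet <- sort(unique(tr$symbol))
  if (anyDuplicated(paste(tr$from, tr$symbol)))
    stop("unifilarity violated: duplicate (state, symbol) transition")
  S <- length(states); K <- length(alphabet)
  target <- matrix(0L, S, K, dimnames = list(states, alphabet))
  prob <- matrix(0, S, K, dimnames = list(states, alphabet))
  fi <- match(tr$from, states); ai <- match(tr$symbol, alphabet)
  ti <- match(tr$to, states)
  if (anyNA(fi) || anyNA(ai) || anyNA(ti))
    stop("transition refers to unknown state or symbol")
  target[cbind(fi, ai)] <- ti
  prob[cbind(fi, ai)] <- tr$p
  m <- new_machine(states, alphabet, target, prob, notes = notes)
  validate_machine(m)
  m
}

# Cheap constructor used internally on pre-validated matrices.
new_machine <- function(states, alphabet, target, prob,
                        transient = NULL, notes = "") {
  if (is.null(transient)) transient <- rep(FALSE, length(states))
  dimnames(target) <- dimnames(prob) <- list(states, alphabet)
  structure(list(states = states, alphabet = alphabet,
                 target = target, prob = prob,
                 transient = transient, notes = notes),
            class = "machine")
}

#' Validate machine invariants
#'
#' Checks row stochasticity (within `tol`), strictly positive stored
#' transition probabilities, agreement of the `target`/`prob` supports, and a
#' nonempty recurrent part (at least one terminal strongly connected
#' component).
#'
#' @param m a [machine].
#' @param tol tolerance for row-sum checks (default `1e-9`).
#' @return `m`, invisibly; errors on violation.
#' @export
validate_machine <- function(m, tol = 1e-9) {
  stopifnot(inherits(m, "machine"))
  if (any((m$target > 0) != (m$prob > 0)))
    stop("target/probability supports disagree")
  has_edge <- rowSums(m$target > 0) > 0
  if (!all(has_edge))
    stop("state(s) without outgoing transitions: ",
         paste(m$states[!has_edge], collapse = ", "))
  rs <- rowSums(m$prob)
  if (any(abs(rs - 1) > tol))
    stop("transition rows not stochastic (max deviation ",
         format(max(abs(rs - 1))), ")")
  if (any(m$prob < 0))
    stop("negative transition probability")
  rec <- recurrent_states(m)
  if (!any(rec)) stop("empty recurrent part")
  invisible(m)
}

#' Extract the transition table of a machine
#'
#' @param m a [machine].
#' @return data frame with columns `from`, `symbol`, `to`, `p`, sorted by
#'   `(from, symbol)`.
#' @export
transitions <- function(m) {
  idx <- which(m$target > 0, arr.ind = TRUE)
  df <- data.frame(from = m$states[idx[, 1]],
                   symbol = m$alphabet[idx[, 2]],
                   to = m$states[m$target[idx]],
                   p = m$prob[idx],
                   stringsAsFactors = FALSE)
  df[order(df$from, df$symbol), , drop = FALSE]
}

n_states <- function(m) length(m$states)
n_edges <- function(m) sum(m$target > 0)

#' @export
print.machine <- function(x, ...) {
  cat(sprintf("<machine: %d state(s), alphabet {%s}, %d transition(s)>\n",
              n_states(x), paste(x$alphabet, collapse = ","), n_edges(x)))
  if (any(x$transient)) {
    cat("transient:", paste(x$states[x$transient], collapse = ", "), "\n")
  }
  tr <- transitions(x)
  for (i in seq_len(nrow(tr))) {
    cat(sprintf("  %s --%s (%.6g)--> %s\n",
                tr$from[i], tr$symbol[i], tr$p[i], tr$to[i]))
  }
  if (nzchar(x$notes)) cat("notes:", x$notes, "\n")
  invisible(x)
}

# ---- recurrent structure -------------------------------------------------

# state-to-state boolean adjacency of the transition support
support_adjacency <- function(target) {
  S <- nrow(target)
  adj <- matrix(FALSE, S, S)
  for (s in seq_len(S)) {
    ts <- target[s, ]
    ts <- ts[ts > 0]
    adj[s, ts] <- TRUE
  }
  adj
}

# Strongly connected components of the support graph via boolean reachability
# closure; small-state machines make this O(|S|^3 log |S|) cost negligible.
# Returns list(comp = integer component id per state, terminal = logical per
# component id).  igraph provides the same decomposition and is used as the
# independent oracle in the test suite; this in-package version keeps the
# per-generation hot loop dependency-free and allocation-light.
support_components <- function(target) {
  S <- nrow(target)
  adj <- support_adjacency(target)
  reach <- adj | diag(TRUE, S)
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(S)
  cid <- 0L
  for (s in seq_len(S)) {
    if (comp[s] == 0L) {
      cid <- cid + 1L
      members <- which(reach[s, ] & reach[, s])
      comp[members] <- cid
    }
  }
  terminal <- logical(cid)
  for (k in seq_len(cid)) {
    members <- which(comp == k)
    out <- unique(comp[unlist(lapply(members, function(s) {
      ts <- target[s, ]; ts[ts > 0]
    }))])
    terminal[k] <- all(out == k)
  }
  list(comp = comp, terminal = terminal)
}

# Logical vector: which states belong to a terminal (recurrent) SCC.
recurrent_states <- function(m) {
  sc <- support_components(m$target)
  sc$terminal[sc$comp]
}

#' Stationary distribution of a machine
#'
#' The stationary causal-state distribution \eqn{\pi}, computed as the left
#' unit eigenvector of the state-to-state transition matrix restricted to the
#' machine's recurrent component (its terminal strongly connected component).
#' Transient states receive probability zero.
#'
#' @param m a [machine].
#' @return named numeric vector over all states, summing to one.
#' @export
stationary_distribution <- function(m) {
  sc <- support_components(m$target)
  term <- which(sc$terminal)
  if (length(term) > 1) {
    comps <- vapply(term, function(k)
      paste(m$states[sc$comp == k], collapse = ","), character(1))
    stop("multiple terminal components: {",
         paste(comps, collapse = "} {"),
         "}; restrict the machine to one recurrent component")
  }
  idx <- which(sc$comp == term)
  n <- length(idx)
  pi_full <- stats::setNames(numeric(n_states(m)), m$states)
  if (n == 1) {
    pi_full[idx] <- 1
    return(pi_full)
  }
  # state-to-state matrix on the recurrent component
  Tss <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- idx[i]
    for (a in seq_along(m$alphabet)) {
      t2 <- m$target[s, a]
      if (t2 > 0) {
        j <- match(t2, idx)
        Tss[i, j] <- Tss[i, j] + m$prob[s, a]
      }
    }
  }
  A <- rbind(t(Tss) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_rec <- qr.solve(A, b)
  pi_rec[pi_rec < 0] <- 0
  pi_rec <- pi_rec / sum(pi_rec)
  pi_full[idx] <- pi_rec
  pi_full
}

# One-stop per-machine summary used by the drift loop: stationary
# distribution, recurrent mask, allelic entropy/complexity, and the
# stationary probability of the tracked (first-alphabet) symbol.
machine_summary <- function(m) {
  pi <- stationary_distribution(m)
  rec <- pi > 0
  p <- m$prob[rec, , drop = FALSE]
  plogp <- ifelse(p > 0, p * log2(p), 0)
  hmu <- -sum(pi[rec] * rowSums(plogp)) + 0  # + 0 clears IEEE negative zero
  pir <- pi[rec]
  cmu <- -sum(ifelse(pir > 0, pir * log2(pir), 0)) + 0
  p_tracked <- sum(pi[rec] * m$prob[rec, 1])
  list(pi = pi, recurrent = rec, h_mu = hmu, C_mu = cmu,
       p_tracked = p_tracked)
}
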