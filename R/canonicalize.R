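#' Canonicalize a machine
#'
#' Produces the package's canonical presentation of the process generated by
#' `m`:
#'
#' 1. transient states are trimmed (only terminal strongly connected
#'    components of the support graph are kept);
#' 2. states whose future word distributions agree within `tol` are merged by
#'    probabilistic partition refinement (Hopcroft-style: states are split by
#'    their per-symbol (probability, successor-block) signatures until
#'    stable, which resolves all depths up to `|S|`);
#' 3. states are relabeled `A`, `B`, ... in breadth-first order (symbols in
#'    alphabet order) from the state with the lexicographically smallest
#'    future-distribution signature.
#'
#' The result is idempotent and preserves the word distribution of the
#' recurrent process.
#'
#' @param m a [machine].
#' @param tol probability tolerance for state-equivalence (default `1e-9`).
#' @return a [machine].
#' @examples
#' # removing the self-loop of the golden mean leaves the alternating process
#' m <- machine(data.frame(from = c("A", "B"), symbol = c("1", "0"),
#'                         to = c("B", "A"), p = c(1, 1)))
#' canonicalize(m)
#' @export
canonicalize <- function(m, tol = 1e-9) {
  # -- trim transient states -----------------------------------------------
  sc <- support_components(m$target)
  keep <- which(sc$terminal[sc$comp])
  remap <- rep(NA_integer_, n_states(m))
  remap[keep] <- seq_along(keep)
  target <- m$target[keep, , drop = FALSE]
  prob <- m$prob[keep, , drop = FALSE]
  tv <- as.vector(target)
  tv[tv > 0] <- remap[tv[tv > 0]]
  target <- matrix(as.integer(tv), nrow(target), ncol(target))
  S <- nrow(target); K <- ncol(target)
  dig <- max(0L, round(-log10(tol)))

  # -- merge tol-equivalent states by partition refinement -----------------
  block <- rep(1L, S)
  repeat {
    sig <- vapply(seq_len(S), function(s) {
      parts <- character(0)
      for (a in seq_len(K)) {
        if (target[s, a] > 0) {
          parts <- c(parts, sprintf("%d:%s:%d", a,
                                    format(round(prob[s, a], dig)),
                                    block[target[s, a]]))
        }
      }
      paste(parts, collapse = ";")
    }, character(1))
    key <- paste(block, sig)
    newblock <- match(key, unique(key))
    if (identical(as.integer(newblock), block)) break
    block <- as.integer(newblock)
  }
  nb <- max(block)
  tgt2 <- matrix(0L, nb, K)
  prb2 <- matrix(0, nb, K)
  for (b in seq_len(nb)) {
    members <- which(block == b)
    for (a in seq_len(K)) {
      t1 <- target[members, a]
      if (any(t1 > 0)) {
        tgt2[b, a] <- block[t1[t1 > 0][1]]
        prb2[b, a] <- mean(prob[members, a])
      }
    }
    s <- sum(prb2[b, ])
    prb2[b, ] <- prb2[b, ] / s
  }

  # -- canonical relabeling ------------------------------------------------
  keys <- vapply(seq_len(nb), function(s)
    future_key(tgt2, prb2, s, depth = min(nb, 8L), dig = dig), character(1))
  seen <- logical(nb)
  order_out <- integer(0)
  while (length(order_out) < nb) {
    cand <- which(!seen)
    root <- cand[order(keys[cand])[1]]
    queue <- root
    seen[root] <- TRUE
    while (length(queue)) {
      s <- queue[1]; queue <- queue[-1]
      order_out <- c(order_out, s)
      for (a in seq_len(K)) {
        t2 <- tgt2[s, a]
        if (t2 > 0 && !seen[t2]) {
          seen[t2] <- TRUE
          queue <- c(queue, t2)
        }
      }
    }
  }
  rank <- match(seq_len(nb), order_out)
  labels <- if (nb <= 26) LETTERS[seq_len(nb)] else sprintf("S%02d", seq_len(nb))
  tgt3 <- matrix(0L, nb, K)
  prb3 <- matrix(0, nb, K)
  for (s in seq_len(nb)) {
    r <- rank[s]
    for (a in seq_len(K)) {
      if (tgt2[s, a] > 0) {
        tgt3[r, a] <- rank[tgt2[s, a]]
        prb3[r, a] <- prb2[s, a]
      }
    }
  }
  new_machine(labels, m$alphabet, tgt3, prb3, notes = m$notes)
}

# Serialized future word distribution of `s` down to `depth`; label-free, so
# usable as a canonical ordering key.
future_key <- function(target, prob, s, depth, dig = 9L) {
  words <- ""
  st <- s
  pr <- 1
  K <- ncol(target)
  for (d in seq_len(depth)) {
    nw <- character(0); ns <- integer(0); np <- numeric(0)
    for (i in seq_along(words)) {
      for (a in seq_len(K)) {
        t2 <- target[st[i], a]
        if (t2 > 0) {
          nw <- c(nw, paste0(words[i], a))
          ns <- c(ns, t2)
          np <- c(np, pr[i] * prob[st[i], a])
        }
      }
    }
    words <- nw; st <- ns; pr <- np
  }
  agg <- tapply(pr, words, sum)
  agg <- agg[order(names(agg))]
  paste(sprintf("%s=%s", names(agg), format(round(agg, dig))), collapse = ",")
}
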