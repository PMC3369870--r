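#' Generate a population sample from a machine
#'
#' Walks the machine for `length` steps, emitting one allele per step.  The
#' start state is drawn from the stationary distribution of the recurrent
#' component unless `start` is given, so samples are stationary.  A
#' population is an *ordered* string of alleles: with the haploid convention
#' the sample length equals the number of individuals `N`; under the diploid
#' convention callers pass `length = 2 * N`.
#'
#' @param m a [machine].
#' @param length sample length `M >= 1` (number of alleles).
#' @param start optional start state identifier; default samples from
#'   [stationary_distribution()].
#' @return character vector of `length` symbols.
#' @examples
#' set.seed(1)
#' paste(generate_population(canonical_machine("alternating"), 6),
#'       collapse = "")
#' @export
generate_population <- function(m, length, start = NULL) {
  stopifnot(length >= 1)
  if (is.null(start)) {
    pi <- stationary_distribution(m)
    start_i <- sample.int(n_states(m), 1, prob = pi)
  } else {
    start_i <- match(start, m$states)
    if (is.na(start_i)) stop("unknown start state: ", start)
  }
  syms <- cpp_generate(m$target, m$prob, start_i, as.integer(length))
  m$alphabet[syms]
}

# convert a sample (character vector or single string) to 1-based symbol ints
symbols_to_int <- function(m, symbols) {
  if (length(symbols) == 1 && nchar(symbols[1]) > 1 &&
      all(nchar(m$alphabet) == 1)) {
    symbols <- strsplit(symbols, "")[[1]]
  }
  si <- match(symbols, m$alphabet)
  if (anyNA(si))
    stop("symbol(s) outside machine alphabet: ",
         paste(unique(symbols[is.na(si)]), collapse = ", "))
  as.integer(si)
}

#' Parse a population sample through a machine
#'
#' Follows the unique unifilar path from `start`, accumulating per-edge counts
#' and the base-2 log-likelihood.  If a required transition is absent, the
#' log-likelihood is `-Inf` and the counts cover only the parsed prefix.  With
#' `start = "best"` all start states are evaluated and the
#' maximum-likelihood parse is returned, ties broken by state-identifier
#' order.
#'
#' @param m a [machine].
#' @param symbols character vector of alleles (or one string of single-character
#'   symbols).
#' @param start start state identifier, or `"best"`.
#' @return list with elements `start_state`, `state_path`, `edge_counts`
#'   (`|S| x |A|` integer matrix), `log_likelihood` (base 2) and `complete`.
#' @export
parse_population <- function(m, symbols, start = "best") {
  si <- symbols_to_int(m, symbols)
  if (identical(start, "best")) {
    best <- NULL
    for (s in order(m$states)) {
      res <- cpp_parse(m$target, m$prob, si, s)
      if (is.null(best) || res$log_likelihood > best$log_likelihood) {
        best <- res
        best$start <- s
      }
    }
    res <- best
    start_i <- res$start
  } else {
    start_i <- match(start, m$states)
    if (is.na(start_i)) stop("unknown start state: ", start)
    res <- cpp_parse(m$target, m$prob, si, start_i)
  }
  counts <- res$counts
  dimnames(counts) <- list(m$states, m$alphabet)
  path <- res$path[seq_len(res$parsed + 1)]
  list(start_state = m$states[start_i],
       state_path = m$states[path],
       edge_counts = counts,
       log_likelihood = res$log_likelihood,
       complete = res$complete)
}

#' Re-estimate a machine from a sample
#'
#' Keeps the topology of `m` but replaces transition probabilities by the
#' per-state normalized edge counts of the best-start parse of `symbols`.
#' Transitions with zero count are deleted; states never left during the
#' parse keep their previous outgoing distribution and are flagged transient.
#'
#' @param m a [machine].
#' @param symbols population sample, parseable by `m`.
#' @return a [machine] with the same (or reduced) topology.
#' @examples
#' reestimate(canonical_machine("fair_coin"), c("H", "H", "H", "T"))
#' @export
reestimate <- function(m, symbols) {
  pr <- parse_population(m, symbols, start = "best")
  if (!is.finite(pr$log_likelihood))
    stop("sample cannot be parsed by the machine; re-estimation undefined")
  counts <- pr$edge_counts
  visits <- rowSums(counts)
  target <- m$target
  prob <- m$prob
  visited <- visits > 0
  for (s in which(visited)) {
    target[s, counts[s, ] == 0] <- 0L
    prob[s, ] <- counts[s, ] / visits[s]
  }
  new_machine(m$states, m$alphabet, target, prob,
              transient = !visited, notes = m$notes)
}
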