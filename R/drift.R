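#' Run one structural-drift realization
#'
#' The sequential-learning loop: each generation `t` the current machine
#' generates an ordered population of `M` alleles; with innovation enabled a
#' cloned-state proposal may be accepted by likelihood; the machine is then
#' re-estimated from the sample (zero-count edges deleted) and tested for
#' AICc-penalized structural loss; the loop stops when the resulting machine
#' reaches structural stasis (vanishing allelic entropy) or
#' `cfg$max_generations`.
#'
#' @param m0 initial generator, a [machine].
#' @param M sample length (alleles per generation; haploid `M = N`).
#' @param cfg a [psv_config()].
#' @param record `"full"` keeps a per-generation record table (generation,
#'   state/edge counts, `h_mu`, `C_mu`, tracked-symbol probability, subspace
#'   signature, structural event); `"minimal"` keeps only scalar summaries,
#'   which is substantially faster for large ensembles.
#' @param seed optional seed (overrides `cfg$rng_seed`).
#' @return object of class `drift_trajectory`: list with `records` (data
#'   frame or `NULL`), `stasis_time`, `terminal_status` (`"stasis"` or
#'   `"max_generations"`), `stasis_machine` (or `NULL`), `terminal_machine`,
#'   `max_states`, `M`, `alphabet`.
#' @examples
#' traj <- run_drift(canonical_machine("golden_mean", p = 0.5), M = 100,
#'                   cfg = psv_config(innovation_rate = 0), seed = 42)
#' traj$stasis_time
#' @export
run_drift <- function(m0, M, cfg = psv_config(),
                      record = c("full", "minimal"), seed = NULL) {
  record <- match.arg(record)
  seed <- if (!is.null(seed)) seed else cfg$rng_seed
  if (!is.null(seed)) set.seed(seed)
  validate_machine(m0)
  m <- m0
  info <- machine_summary(m)
  full <- record == "full"
  cap <- 64L
  gen_v <- integer(cap); ns_v <- integer(cap); ne_v <- integer(cap)
  h_v <- numeric(cap); c_v <- numeric(cap); pt_v <- numeric(cap)
  sig_v <- character(cap); ev_v <- character(cap)
  nrec <- 0L
  push <- function(gen, ns, ne, h, cc, pt, sig, ev) {
    nrec <<- nrec + 1L
    if (nrec > cap) {
      cap <<- cap * 2L
      length(gen_v) <<- cap; length(ns_v) <<- cap; length(ne_v) <<- cap
      length(h_v) <<- cap; length(c_v) <<- cap; length(pt_v) <<- cap
      length(sig_v) <<- cap; length(ev_v) <<- cap
    }
    gen_v[nrec] <<- gen; ns_v[nrec] <<- ns; ne_v[nrec] <<- ne
    h_v[nrec] <<- h; c_v[nrec] <<- cc; pt_v[nrec] <<- pt
    sig_v[nrec] <<- sig; ev_v[nrec] <<- ev
  }
  sig <- if (full) subspace_signature(m) else NA_character_
  if (full) push(0L, n_states(m), n_edges(m), info$h_mu, info$C_mu,
                 info$p_tracked, sig, "none")
  t <- 0L
  max_states <- n_states(m)
  while (info$h_mu >= cfg$stasis_tol && t < cfg$max_generations) {
    start_i <- if (sum(info$recurrent) == 1) which(info$recurrent) else
      sample.int(n_states(m), 1, prob = info$pi)
    si <- cpp_generate(m$target, m$prob, start_i, as.integer(M))
    event <- "none"
    cand <- m
    if (cfg$innovation_rate > 0) {
      for (r in seq_len(cfg$innovation_rate)) {
        res <- innovate_impl(cand, si, cfg)
        if (res$accepted) {
          cand <- res$machine
          event <- "innovation_accepted"
        }
      }
    }
    prev_ns <- n_states(m); prev_ne <- n_edges(m)
    m2 <- reestimate_int(cand, si)
    m <- try_loss_int(m2, si, cfg)
    if (n_states(m) != n_states(m2) || n_edges(m) != n_edges(m2)) {
      event <- if (event == "none") "loss_merge"
               else paste(event, "loss_merge", sep = "+")
    }
    t <- t + 1L
    info <- machine_summary(m)
    max_states <- max(max_states, n_states(m))
    if (full) {
      topo_changed <- event != "none" ||
        n_states(m) != prev_ns || n_edges(m) != prev_ne
      if (topo_changed) {
        new_sig <- subspace_signature(m)
        if (!identical(new_sig, sig)) {
          event <- if (event == "none") "subspace_jump"
                   else paste(event, "subspace_jump", sep = "+")
          sig <- new_sig
        }
      }
      push(t, n_states(m), n_edges(m), info$h_mu, info$C_mu,
           info$p_tracked, sig, event)
    }
  }
  absorbed <- info$h_mu < cfg$stasis_tol
  records <- if (full) {
    idx <- seq_len(nrec)
    data.frame(generation = gen_v[idx], n_states = ns_v[idx],
               n_edges = ne_v[idx], h_mu = h_v[idx], C_mu = c_v[idx],
               p_tracked = pt_v[idx], signature = sig_v[idx],
               event = ev_v[idx], stringsAsFactors = FALSE)
  } else NULL
  structure(list(records = records,
                 stasis_time = if (absorbed) t else NA_integer_,
                 terminal_status = if (absorbed) "stasis" else "max_generations",
                 stasis_machine = if (absorbed) m else NULL,
                 terminal_machine = m,
                 max_states = max_states,
                 M = M, alphabet = m0$alphabet),
            class = "drift_trajectory")
}

# fast-path internals operating on pre-converted integer symbols -----------

reestimate_int <- function(m, si) {
  best <- NULL
  for (s in seq_len(n_states(m))) {
    res <- cpp_parse(m$target, m$prob, si, s)
    if (is.null(best) || res$log_likelihood > best$log_likelihood) best <- res
  }
  if (!is.finite(best$log_likelihood))
    stop("sample cannot be parsed by the machine")
  counts <- best$counts
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

try_loss_int <- function(m, si, cfg) {
  if (!any(m$prob > 0 & m$prob < cfg$merge_threshold)) return(m)
  try_loss(m, m$alphabet[si], cfg)
}

#' @export
print.drift_trajectory <- function(x, ...) {
  cat(sprintf("<drift trajectory: M=%d, %s%s, max states %d>\n", x$M,
              x$terminal_status,
              if (x$terminal_status == "stasis")
                sprintf(" at generation %d", x$stasis_time) else "",
              x$max_states))
  invisible(x)
}

#' Run an ensemble of independent drift realizations
#'
#' Child seeds are spawned deterministically from `seed`, so ensembles are
#' bitwise reproducible and realizations independent.
#'
#' @inheritParams run_drift
#' @param n_realizations number of realizations.
#' @param seed master seed for the ensemble.
#' @return object of class `drift_ensemble`: a list of
#'   [run_drift()] trajectories with attributes `M` and `alphabet`.
#' @export
run_ensemble <- function(m0, M, cfg = psv_config(), n_realizations,
                         record = c("minimal", "full"), seed = NULL) {
  record <- match.arg(record)
  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(.Machine$integer.max, n_realizations)
  trajs <- lapply(seq_len(n_realizations), function(i)
    run_drift(m0, M, cfg, record = record, seed = child[i]))
  structure(trajs, class = "drift_ensemble", M = M, alphabet = m0$alphabet)
}

#' Stasis times of an ensemble
#'
#' @param x a `drift_ensemble` (or list of trajectories).
#' @return integer vector of stasis times (`NA` for unabsorbed realizations).
#' @export
stasis_times <- function(x) {
  vapply(x, function(tr) as.integer(tr$stasis_time), integer(1))
}

#' @export
summary.drift_ensemble <- function(object, ...) {
  st <- stasis_times(object)
  ok <- !is.na(st)
  data.frame(n = length(st), absorbed = sum(ok),
             mean_stasis = mean(st[ok]),
             se = stats::sd(st[ok]) / sqrt(sum(ok)))
}

#' @export
print.drift_ensemble <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "<drift ensemble: %d realization(s), %d absorbed, mean stasis %.2f (se %.2f)>\n",
    s$n, s$absorbed, s$mean_stasis, s$se))
  invisible(x)
}
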