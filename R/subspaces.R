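#' Isostructural subspace signature
#'
#' A label for the isostructural subspace of `m`: the probability-free
#' transition support of the canonicalized machine, encoded canonically so
#' that the label is invariant under state relabeling and under any change of
#' positive transition probabilities.  Machines in the same subspace share a
#' fixed architecture of states and transitions and differ only by parameter
#' diffusion; a change of signature along a drift trajectory is a subspace
#' jump.
#'
#' @param m a [machine].
#' @return character scalar.
#' @examples
#' subspace_signature(canonical_machine("biased_coin", p = 0.3)) ==
#'   subspace_signature(canonical_machine("biased_coin", p = 0.7))
#' @export
subspace_signature <- function(m) {
  mc <- canonicalize(m)
  support_code(mc$target, mc$alphabet)
}

support_code <- function(target, alphabet) {
  S <- nrow(target); K <- ncol(target)
  codes <- character(0)
  for (root in seq_len(S)) {
    lab <- rep(NA_integer_, S)
    lab[root] <- 1L
    nxt <- 2L
    queue <- root
    while (length(queue)) {
      s <- queue[1]; queue <- queue[-1]
      for (a in seq_len(K)) {
        t2 <- target[s, a]
        if (t2 > 0 && is.na(lab[t2])) {
          lab[t2] <- nxt
          nxt <- nxt + 1L
          queue <- c(queue, t2)
        }
      }
    }
    if (anyNA(lab)) next  # root does not reach every state
    edges <- character(0)
    for (s in seq_len(S)) {
      for (a in seq_len(K)) {
        if (target[s, a] > 0) {
          edges <- c(edges, sprintf("%d.%s>%d", lab[s], alphabet[a],
                                    lab[target[s, a]]))
        }
      }
    }
    codes <- c(codes, paste0(S, "|", paste(sort(edges), collapse = ";")))
  }
  if (!length(codes)) {
    # disconnected recurrent part: signature per component, sorted
    sc <- support_components(target)
    parts <- vapply(sort(unique(sc$comp)), function(k) {
      idx <- which(sc$comp == k)
      sub <- target[idx, , drop = FALSE]
      sv <- as.vector(sub)
      sv[sv > 0] <- match(sv[sv > 0], idx)
      support_code(matrix(as.integer(sv), length(idx), ncol(target)), alphabet)
    }, character(1))
    return(paste(sort(parts), collapse = "&"))
  }
  min(codes)
}

# Reference signatures for a binary alphabet: both symbol roles of the
# named two-state processes, the coin subspaces, and the alternating cycle.
# Memoised per alphabet.
.sig_env <- new.env(parent = emptyenv())

signature_class_table <- function(alphabet) {
  key <- paste(alphabet, collapse = "\r")
  if (!is.null(.sig_env[[key]])) return(.sig_env[[key]])
  tab <- character(0)
  mk <- function(df) machine(df, alphabet = alphabet)
  for (s in alphabet) {
    tab[subspace_signature(mk(data.frame(
      from = "A", symbol = s, to = "A", p = 1)))] <- "FC"
  }
  if (length(alphabet) == 2) {
    a <- alphabet[1]; b <- alphabet[2]
    tab[subspace_signature(mk(data.frame(
      from = c("A", "A"), symbol = c(a, b), to = c("A", "A"),
      p = c(0.5, 0.5))))] <- "BC"
    tab[subspace_signature(mk(data.frame(
      from = c("A", "B"), symbol = c(a, b), to = c("B", "A"),
      p = c(1, 1))))] <- "AP"
    for (ord in list(c(a, b), c(b, a))) {
      u <- ord[1]; v <- ord[2]  # v = constrained symbol
      tab[subspace_signature(mk(data.frame(
        from = c("A", "A", "B"), symbol = c(u, v, u), to = c("A", "B", "A"),
        p = c(0.5, 0.5, 1))))] <- "GM"
      tab[subspace_signature(mk(data.frame(
        from = c("A", "A", "B"), symbol = c(u, v, v), to = c("A", "B", "A"),
        p = c(0.5, 0.5, 1))))] <- "EP"
    }
  }
  .sig_env[[key]] <- tab
  tab
}

#' Classify a subspace signature
#'
#' Maps signatures of the canonical subspaces to short class labels: `"FC"`
#' (fixed coin, either allele), `"BC"` (biased/fair coin), `"AP"`
#' (alternating), `"GM"` (golden mean, either constrained symbol), `"EP"`
#' (even process).  Unrecognized signatures are returned unchanged.
#'
#' @param x a [machine] or a signature string.
#' @param alphabet required when `x` is a signature string.
#' @return character label(s).
#' @export
signature_class <- function(x, alphabet = NULL) {
  if (inherits(x, "machine")) {
    alphabet <- x$alphabet
    x <- subspace_signature(x)
  }
  if (is.null(alphabet)) stop("alphabet required to classify a signature string")
  tab <- signature_class_table(alphabet)
  out <- unname(tab[x])
  ifelse(is.na(out), x, out)
}

#' Period of a stasis machine
#'
#' For a machine at structural stasis (zero allelic entropy) the recurrent
#' part is a single deterministic cycle; the period is the length of that
#' cycle after canonicalization (so e.g. a two-state cycle emitting the same
#' allele twice reduces to period 1).
#'
#' @param m a [machine] with `allelic_entropy(m) == 0`.
#' @return integer period.
#' @export
stasis_period <- function(m) {
  if (!is_stasis(m)) stop("machine is not at structural stasis")
  n_states(canonicalize(m))
}

#' Complexity-entropy diagram points
#'
#' One `(h_mu, C_mu)` point per generation per realization, labeled by the
#' isostructural-subspace signature (points within a subspace share a label,
#' which is how the diagram's curves are colored).
#'
#' @param x a `drift_ensemble` (or list of trajectories) run with
#'   `record = "full"`.
#' @return data frame with columns `realization`, `generation`, `h_mu`,
#'   `C_mu`, `signature`, `class`.
#' @export
ce_diagram <- function(x) {
  alphabet <- attr(x, "alphabet")
  out <- lapply(seq_along(x), function(i) {
    r <- x[[i]]$records
    if (is.null(r)) stop("ce_diagram requires trajectories run with record = 'full'")
    data.frame(realization = i, generation = r$generation,
               h_mu = r$h_mu, C_mu = r$C_mu, signature = r$signature,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$class <- signature_class(out$signature, alphabet %||% attr(x[[1]], "alphabet") %||% x[[1]]$alphabet)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pathway decomposition of stasis times
#'
#' Groups absorbed realizations by pathway — the ordered sequence of
#' distinct isostructural subspaces visited from the initial process to its
#' stasis point — and decomposes the mean stasis time as the
#' pathway-probability-weighted sum of per-pathway times, each of which is
#' the sum of mean dwell times in the pathway's subspaces.  Dwell time counts
#' generations from subspace entry (inclusive) to exit (exclusive), which
#' makes both decompositions exact accounting identities on the ensemble.
#' Entry parameters (the stationary tracked-symbol probability at the first
#' generation inside each subspace) are recorded at every jump.
#'
#' @param x a `drift_ensemble` run with `record = "full"`.
#' @return list of class `stasis_decomposition` with elements `pathways`
#'   (pathway, n, weight, mean_time, se), `dwells` (per-pathway per-subspace
#'   mean dwell times), `segments` (one row per visited subspace per
#'   realization, with entry generation, entry tracked-symbol probability and
#'   dwell), `total_mean`, `reconstructed_mean`, `n_excluded` (unabsorbed
#'   realizations, excluded with a warning).
#' @export
decompose_stasis_times <- function(x) {
  alphabet <- attr(x, "alphabet") %||% x[[1]]$alphabet
  absorbed <- vapply(x, function(tr) tr$terminal_status == "stasis", logical(1))
  n_excl <- sum(!absorbed)
  if (n_excl > 0)
    warning(n_excl, " unabsorbed trajectories excluded from the decomposition")
  trajs <- x[absorbed]
  segs <- lapply(seq_along(trajs), function(i) {
    r <- trajs[[i]]$records
    if (is.null(r)) stop("decompose_stasis_times requires record = 'full'")
    stime <- trajs[[i]]$stasis_time
    rl <- rle(r$signature)
    ends <- cumsum(rl$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    entry_gen <- r$generation[starts]
    dwell <- c(diff(entry_gen), stime - entry_gen[length(entry_gen)])
    cls <- signature_class(rl$values, alphabet)
    data.frame(realization = which(absorbed)[i],
               pathway = paste(cls, collapse = "|"),
               step = seq_along(starts),
               signature = rl$values, class = cls,
               entry_generation = entry_gen,
               entry_p = r$p_tracked[starts],
               dwell = dwell,
               stasis_time = stime,
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  per_traj <- segs[!duplicated(segs$realization),
                   c("realization", "pathway", "stasis_time")]
  n_abs <- nrow(per_traj)
  pw <- split(per_traj, per_traj$pathway)
  pathways <- do.call(rbind, lapply(pw, function(d) {
    data.frame(pathway = d$pathway[1], n = nrow(d),
               weight = nrow(d) / n_abs,
               mean_time = mean(d$stasis_time),
               se = stats::sd(d$stasis_time) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(pathways) <- NULL
  dw <- split(segs, list(segs$pathway, segs$step), drop = TRUE)
  dwells <- do.call(rbind, lapply(dw, function(d) {
    data.frame(pathway = d$pathway[1], step = d$step[1],
               class = d$class[1], n = nrow(d),
               mean_dwell = mean(d$dwell),
               mean_entry_p = mean(d$entry_p),
               stringsAsFactors = FALSE)
  }))
  dwells <- dwells[order(dwells$pathway, dwells$step), ]
  rownames(dwells) <- NULL
  structure(list(pathways = pathways, dwells = dwells, segments = segs,
                 total_mean = mean(per_traj$stasis_time),
                 reconstructed_mean = sum(pathways$weight * pathways$mean_time),
                 n_excluded = n_excl),
            class = "stasis_decomposition")
}

#' @export
print.stasis_decomposition <- function(x, ...) {
  cat(sprintf("<stasis decomposition: mean %.3f over %d pathway(s)>\n",
              x$total_mean, nrow(x$pathways)))
  print(x$pathways)
  invisible(x)
}
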