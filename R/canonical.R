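#' Canonical process library
#'
#' Construct the minimal unifilar presentation of a named canonical process.
#' Available processes:
#'
#' * `"alternating"`: period-2 process over `{0,1}`; two causal states, two
#'   deterministic transitions.
#' * `"fair_coin"`: IID fair binary process over `{H,T}`; one causal state.
#' * `"biased_coin"`: IID process with `Pr[H] = p`; degenerate biases
#'   `p = 0` or `p = 1` yield the one-transition fixed coin.
#' * `"fixed_coin"`: deterministic repetition of a single `symbol`.
#' * `"golden_mean"`: two states; the branching state emits the repeated
#'   symbol as a self-loop and emits the constrained symbol (consecutive
#'   occurrences forbidden, by default `forbid = "1"`) with probability `p`;
#'   the forced state returns while emitting the unconstrained symbol.
#' * `"even"`: two states; blocks of the constrained symbol (default `"1"`)
#'   have even length; the branching state enters the block with
#'   probability `p`.
#' * `"period_n"`: deterministic cycle emitting `phase`, reduced to its
#'   minimal presentation.
#'
#' @param name process name (see above).
#' @param p branching probability in `[0,1]` where the process branches.
#' @param symbol emitted symbol for `"fixed_coin"`.
#' @param forbid constrained symbol for `"golden_mean"` / `"even"`.
#' @param phase symbol string defining the cycle for `"period_n"`.
#' @return a [machine].
#' @examples
#' canonical_machine("golden_mean", p = 0.5)
#' canonical_machine("period_n", phase = "0011")
#' @export
canonical_machine <- function(name, p = 0.5, symbol = "H",
                              forbid = "1", phase = NULL) {
  name <- match.arg(name, c("alternating", "fair_coin", "biased_coin",
                            "fixed_coin", "golden_mean", "even", "period_n"))
  chk_p <- function(p, open = TRUE) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p))
      stop("p must be a single number")
    if (open && (p <= 0 || p >= 1))
      stop("branching probability must lie strictly in (0, 1)")
    if (p < 0 || p > 1) stop("probability outside [0, 1]")
  }
  switch(name,
    alternating = machine(data.frame(
      from = c("A", "B"), symbol = c("0", "1"), to = c("B", "A"), p = c(1, 1)),
      alphabet = c("0", "1"), notes = "alternating process"),
    fair_coin = machine(data.frame(
      from = c("A", "A"), symbol = c("H", "T"), to = c("A", "A"),
      p = c(0.5, 0.5)), alphabet = c("H", "T"), notes = "fair coin process"),
    biased_coin = {
      chk_p(p, open = FALSE)
      if (p == 0) return(canonical_machine("fixed_coin", symbol = "T"))
      if (p == 1) return(canonical_machine("fixed_coin", symbol = "H"))
      machine(data.frame(
        from = c("A", "A"), symbol = c("H", "T"), to = c("A", "A"),
        p = c(p, 1 - p)), alphabet = c("H", "T"),
        notes = sprintf("biased coin process, Pr[H]=%g", p))
    },
    fixed_coin = machine(data.frame(
      from = "A", symbol = symbol, to = "A", p = 1),
      alphabet = symbol,
      notes = sprintf("fixed coin process (%s)", symbol)),
    golden_mean = {
      chk_p(p)
      other <- setdiff(c("0", "1"), forbid)
      if (length(other) != 1) stop("forbid must be '0' or '1'")
      machine(data.frame(
        from = c("A", "A", "B"), symbol = c(other, forbid, other),
        to = c("A", "B", "A"), p = c(1 - p, p, 1)),
        alphabet = c("0", "1"),
        notes = sprintf("golden mean process, Pr[%s|branch]=%g", forbid, p))
    },
    even = {
      chk_p(p)
      other <- setdiff(c("0", "1"), forbid)
      if (length(other) != 1) stop("forbid must be '0' or '1'")
      machine(data.frame(
        from = c("A", "A", "B"), symbol = c(other, forbid, forbid),
        to = c("A", "B", "A"), p = c(1 - p, p, 1)),
        alphabet = c("0", "1"),
        notes = sprintf("even process, Pr[%s|branch]=%g", forbid, p))
    },
    period_n = {
      if (is.null(phase) || !nzchar(phase))
        stop("period_n requires a nonempty phase string")
      syms <- strsplit(phase, "")[[1]]
      n <- length(syms)
      states <- sprintf("P%d", seq_len(n))
      m <- machine(data.frame(
        from = states, symbol = syms, to = states[c(seq_len(n)[-1], 1)],
        p = rep(1, n)), alphabet = sort(unique(syms)),
        notes = sprintf("period-%d process '%s'", n, phase))
      canonicalize(m)
    })
}
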