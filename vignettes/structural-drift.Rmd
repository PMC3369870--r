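---
title: "Structural drift: models, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural drift: models, measures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(structdrift)
```

## The model

Classical neutral drift treats a population as an unordered bag of alleles:
each generation resamples $M$ alleles binomially with the current frequency,
the frequency is re-estimated by maximum likelihood, and the walk continues
until fixation or deletion.  `structdrift` generalizes this to *ordered*
populations.  A generation is a length-$M$ string of alleles produced by a
unifilar probabilistic finite-state machine (an $\epsilon$-machine): a set of
causal states $\mathcal{S}$, an allele alphabet $\mathcal{A}$, and per-symbol
transition matrices $T^{(a)}_{\sigma\sigma'}$ giving the probability of
emitting allele $a$ while moving from state $\sigma$ to $\sigma'$.
Unifilarity means the emitted symbol determines the successor state, so a
machine assigns each string a unique path and an exact likelihood.

Sequential learning is the chain $M_0 \to P_0 \to M_1 \to P_1 \to \cdots$:
machine $M_t$ generates population $P_t$; $M_{t+1}$ is estimated from $P_t$;
repeat.  Because samples are finite, the estimated transition probabilities
fluctuate from generation to generation — this sampling variance alone, with
neither mutation nor selection, drives the dynamics.  When the sampling
process is the memoryless biased coin, the chain *is* the classical
Fisher–Wright random walk, and the package reproduces Kimura–Ohta
fixation-time theory (`kimura_t1()`, `kimura_t0()`, `mc_drift()`,
`wf_absorption_times()`).

## Information measures and stasis

Fixation and deletion do not cover everything that can stop an ordered
population from changing: a strictly periodic machine (e.g. the Alternating
Process) produces zero variance between generations while keeping both
alleles at frequency $1/2$.  The package therefore tests for **structural
stasis**: the vanishing of the *allelic entropy*

$$h_\mu \;=\; -\sum_\sigma \pi_\sigma \sum_{a,\sigma'}
  T^{(a)}_{\sigma\sigma'} \log_2 T^{(a)}_{\sigma\sigma'},$$

the entropy rate of the sampling process in bits per allele, computed in
closed form on the recurrent component with $\pi$ the stationary state
distribution (`allelic_entropy()`, `is_stasis()`).  Stasis subsumes
fixation, deletion, and periodicity.  The block entropy $H(L)$ of length-$L$
populations (`population_diversity()`) diverges for generic processes, so it
is used only as a cross-check: its increments $H(L+1) - H(L)$ decrease to
$h_\mu$, which the test suite verifies exhaustively to depth $L = 14$.

The memory of the process is the *allelic complexity*
$C_\mu = -\sum_\sigma \pi_\sigma \log_2 \pi_\sigma$
(`allelic_complexity()`).  The pair $(h_\mu, C_\mu)$ is the
complexity–entropy plane onto which `ce_diagram()` projects trajectories.

```{r}
sapply(list(alternating = canonical_machine("alternating"),
            fair_coin = canonical_machine("fair_coin"),
            golden_mean = canonical_machine("golden_mean", p = 0.5)),
       function(m) c(h_mu = allelic_entropy(m), C_mu = allelic_complexity(m)))
```

Measures are computed on the recurrent component only; transient states
(which arise during drift when a parse no longer visits a state) are
excluded from $\pi$, $h_\mu$ and $C_\mu$.  All logarithms are base 2 and all
units are bits.

## The drift engine and the PSV algorithm

Re-running a full $\epsilon$-machine reconstruction every generation is
expensive and introduces algorithm-specific artifacts.  Instead the engine
uses an explicit innovation/loss proposal scheme in the spirit of Kimura's
pseudo-sampling-variable method:

* **Re-estimation** (`reestimate()`): the sample is fed through the current
  machine (best start state over all candidates, ties by identifier order);
  edge counts are normalized per state.  Transitions with count zero are
  deleted immediately — no pseudocounts — because edge deletion is exactly
  the mechanism by which stasis is reached.  With integer counts, a machine
  at stasis has only probability-1 edges, so $h_\mu$ is *exactly* zero and
  the stasis test needs no floating-point threshold in practice (the default
  tolerance `1e-12` only guards degenerate inputs).
* **Innovation** (`innovate()`): a uniformly chosen state is cloned, each
  incoming transition is independently rerouted to the clone with
  probability $1/2$ (resampled until the split is proper), and Gaussian
  noise (`noise_sigma`, default 0.05) is added to the clone's outgoing
  probabilities, clipped to `[prob_floor, 1]` with `prob_floor = 1e-6` so
  the noise step alone can never delete an edge.  The proposal is kept only
  if it strictly increases the sample likelihood.  We use a uniform prior
  over the two candidate models, reducing the posterior comparison to a
  likelihood comparison; ties keep the smaller incumbent.
* **Loss** (`try_loss()`): when any edge probability falls below
  `merge_threshold`, all pairwise state mergings are formed (unifilarity
  conflicts resolved by recursively merging conflicting targets),
  canonicalized, re-fit to the sample, and scored with AICc; the minimizer
  wins, ties favoring fewer states then fewer edges.

### Parameter counting in the AIC

`model_score()` uses $\mathrm{AIC} = 2k - 2\ln\hat L$ and
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$ with $k$ the number of
**stored transitions**: each stored transition probability is counted as a
model parameter.  The more orthodox count of free parameters (transitions
minus states, since rows are normalized) looks attractive but has a
structural consequence worth spelling out: under it, the two-state golden
mean and the one-state coin carry the *same* penalty ($k = 1$ each), and
because the golden mean's finer partition of contexts never fits a sample it
generated worse than the pooled coin does, the merge would never be
accepted.  The characteristic jump from the golden-mean subspace to the
coin subspace — the phenomenon the subspace decomposition is built to
measure — would be structurally impossible.  Counting stored transitions
restores a penalty difference of one parameter, which makes the merge
acceptable precisely when the rare branch is weakly supported (at
$M = 100$, below a branch probability of roughly $0.05$), i.e. the jump
happens "at very low values" of the branch parameter, where the remaining
coin-diffusion time is short.

### The merge threshold

`merge_threshold` (default 0.05) only gates when merges are *tested*;
acceptance is always decided by the penalized likelihood.  Note that a
threshold of $1/M$ would be unreachable: re-estimated probabilities are
ratios `count / visits` with `visits <= M`, so any surviving edge has
probability at least $1/M$.  The default sits just above the AICc crossover
at the reference sample length $M = 100$, so every merge that could be
accepted is actually tested, and larger thresholds only add rejected tests.
The sensitivity of the jump point to this setting is real and documented
here rather than hidden: users comparing against differently tuned inference
schemes should vary `merge_threshold` and report it.

## Subspaces, signatures, and pathway decomposition

An *isostructural subspace* is implemented as the equivalence class of the
probability-free transition support of the canonicalized machine
(`subspace_signature()`).  This is a checkable, constructive definition:
machines that differ only in positive transition probabilities share a
signature, and a signature change along a trajectory is exactly a topology
change.  Signatures distinguish symbol roles (the golden mean, which forbids
a repeated `1`, differs from the even process, which forces even blocks of
`1`s), so the two one-symbol fixed coins get distinct signatures;
`signature_class()` maps both to the class `"FC"`, since drift through the
coin subspace can fix on either allele and the fixed coin as a *process
class* is symbol-agnostic.

`decompose_stasis_times()` groups absorbed realizations by pathway (the
sequence of distinct subspaces visited) and reports the mean stasis time as
the pathway-weighted sum of per-subspace dwell times.  Dwell time runs from
the entry generation (inclusive) to the exit generation (exclusive), which
makes both decomposition identities *exact* on any ensemble, not
approximations.  Entry parameters are taken from the first per-generation
record inside the new subspace (the stationary probability of the tracked,
first-alphabet symbol); for a coin machine this is its bias, which is what
the dwell-time theory needs.

```{r}
gm <- canonical_machine("golden_mean", p = 0.5)
ens <- run_ensemble(gm, M = 100, cfg = psv_config(innovation_rate = 0),
                    n_realizations = 50, record = "full", seed = 20)
decompose_stasis_times(ens)
```

The coin-subspace dwell after a golden-mean-to-coin jump is itself a
memoryless drift problem started from the entry bias; the test suite checks
it against the exact absorption times of the finite Fisher–Wright chain
(`wf_absorption_times()`).

## What the generator emulates — and what it does not

The simulation conditions used throughout the package's tests are the
reference conditions of the underlying experiments: haploid populations of
`M = 100` ordered alleles for structural drift, `N = 100` diploid
individuals (`M = 200` alleles) for the classical fixation-time
calibration, and 400 realizations per ensemble point.  Within those
conditions the engine reproduces: the Kimura–Ohta fixation/deletion curves;
the statistical equivalence of coin-subspace structural drift and Monte
Carlo frequency drift; the markedly faster stasis of the memoryful golden
mean and even processes; the golden mean's two stasis fates (fixed coin via
the coin subspace, or the alternating machine); and, with innovation
enabled, machines of three or more states and stasis periods beyond 2.

Limits worth keeping in mind:

* Populations are finite symbol strings from finite-state machines.  Real
  populations have unordered or spatially structured components, mutation,
  and selection; none of these are modeled (mutation/selection operators are
  out of scope by design).
* Passing ensemble checks at $M = 100$ says nothing about asymptotics:
  every interesting behavior here is a finite-sample effect and disappears
  as $M \to \infty$.
* The innovation/loss proposal scheme is a surrogate for full
  reconstruction.  Its noise scale, proposal rate, and merge threshold are
  tunables with no canonical values; the defaults (`noise_sigma = 0.05`,
  one proposal per generation, `merge_threshold = 0.05`) are choices, and
  quantities that depend on them — notably the inventory of stasis periods
  reachable with innovation enabled — should be read qualitatively.

## Numerical choices

* Start states for generation are drawn from the stationary distribution,
  so samples are stationary from the first symbol.
* Parsing uses the maximum-likelihood start state with ties broken by
  state-identifier order; all likelihoods are base-2 and converted to
  natural log only inside the AIC.
* The stationary distribution is the left unit eigenvector of the
  state-to-state matrix on the unique terminal strongly connected
  component; machines with several terminal components are refused with an
  error naming the components.
* `canonicalize()` merges states whose per-symbol (probability, successor
  block) signatures agree within `tol = 1e-9` by partition refinement, then
  relabels states breadth-first from the state with the lexicographically
  smallest future-distribution key, making the result idempotent.
* Probability comparisons default to `1e-9`; row-stochasticity is enforced
  to the same tolerance after every operation.
* Master seeds spawn per-realization child seeds (`run_ensemble()`), so
  ensembles are bitwise reproducible and trivially parallelizable.
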