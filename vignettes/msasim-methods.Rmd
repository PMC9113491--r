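---
title: "Simulating alignments along trees: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating alignments along trees: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

msasim evolves a root sequence along a rooted phylogeny under a
continuous-time Markov substitution model, optionally with site-rate
heterogeneity and an insertion–deletion process, and assembles the results
into a gapped multiple sequence alignment. This vignette explains the model,
the two branch-evolution algorithms and the switch between them, and records
the design decisions that were genuinely open, so that a green test suite can
be read for exactly what it does and does not establish.

## The substitution model

A model is an instantaneous rate matrix $Q = (q_{xy})$ over a finite state
alphabet $\Sigma$ together with stationary frequencies $\pi$. msasim always
normalizes $Q$ in two steps: the diagonal is set so that every row sums to
zero, and the whole matrix is rescaled so that the expected substitution rate
at stationarity is one,

$$\sum_x \pi_x q_{xx} = -1 .$$

With this convention a branch length $t$ is the expected number of
substitutions per site, which is what likelihood software prints on its
trees. `build_model()` offers JC, K2P, HKY and GTR (exchangeabilities in the
conventional AC, AG, AT, CG, CT, GT order) plus `USER` matrices over
arbitrary alphabets; amino-acid models are supported only through `USER`
matrices — no empirical exchangeability tables are bundled.

Frequencies that miss a sum of 1 by at most $10^{-6}$ are renormalized
silently (rounding in user input); larger discrepancies are treated as user
error and rejected. The named model families require strictly positive
frequencies; `normalize_rate_matrix()` itself accepts zeros (the weighted
trace only needs to stay negative), which is how degenerate stationary
distributions can be exercised in tests.

Transition matrices $P(t, r) = e^{Qtr}$ are computed from a cached spectral
decomposition for reversible models. The decomposition is performed on the
similar symmetric matrix $D^{1/2} Q D^{-1/2}$ with $D = \mathrm{diag}(\pi)$,
which guarantees real eigenvalues — the standard trick in phylogenetic
software. Non-reversible (USER) matrices fall back to dense
scaling-and-squaring exponentiation (`Matrix::expm`); the two paths are
cross-checked against each other in the test suite to $10^{-9}$. Entries of
$P$ that come out negative by round-off above $-10^{-12}$ are clamped to zero
and the row renormalized; anything more negative raises an error instead of
being papered over.

## Site-rate heterogeneity

`rate_model()` combines an invariant-site proportion $p_{inv}$ with exactly
one of: discrete Gamma ($k$ equal-probability categories), continuous Gamma,
or free rates. Two conventions had to be chosen because they are not
universal:

* **Category rates use the mean of the Gamma density over each
  inter-quantile interval** (the "mean" discretization), not the median.
  This matches the dominant convention of the likelihood programs this
  simulator feeds, so that a simulated `+G4` alignment is analysed under the
  same discretization it was generated from. Rates are renormalized so the
  category mean is exactly 1.
* **Invariant sites get rate exactly 0 and the variable part is scaled by
  $1/(1-p_{inv})$**, keeping the overall mean rate at 1. The alternative
  (not rescaling) would make realized branch lengths shrink by a factor
  $1-p_{inv}$; with the chosen convention the expected number of
  substitutions per site always equals the branch length, which is the
  interpretation the normalization above promises.

Free-rate weights and rates are taken as given, renormalized to mean 1 with a
warning when they are off.

## Evolving one branch

**Rate-matrix (Gillespie) method.** With the sequence $X$ and per-site rates
$r_i$, the total event rate is $M = S + I + D$ with

$$S = -\sum_i q_{x_i x_i} r_i , \qquad I = r_I (L + 1) , \qquad
  D = r_D (L - 1 + u_D),$$

where $L$ counts non-gap characters, $r_I, r_D$ are indel rates relative to
the substitution rate and $u_D$ is the mean deletion length. Waiting times
are exponential with mean $1/M$; each event is a substitution, insertion or
deletion with probabilities $S/M$, $I/M$, $D/M$. Substitution sites are
picked proportionally to $-q_{x_i x_i} r_i$ (so invariant sites can never be
substituted but can still be deleted), the new state $z$ with probability
$q_{xz}/(-q_{xx})$. The inner loop is implemented in C++ but draws all its
randomness from R's generator, so results are reproducible from `set.seed()`.
$I$ and $D$ are recomputed from the current $L$ at every event rather than
updated incrementally; this is algebraically identical except after a
truncated deletion (below), where the recomputed value is the self-consistent
one. $S$ is refreshed from scratch every $10^6$ events to cap the drift of
incremental updates.

**Probability-matrix method.** Each non-gap site draws its child state from
row $x_i$ of $P(t, r_i)$. With discrete rates only one matrix per distinct
rate is built (at most $k$; invariant sites cost nothing since they cannot
change). With continuous Gamma rates every site has its own effective
distance $t r_i$; the cached eigendecomposition turns this into two dense
matrix products over all sites at once. Indels, if enabled, are then
simulated by the Gillespie loop with $S$ pinned at zero.

**Adaptive switch.** The Gillespie method costs work proportional to the
number of events ($\approx L t$ each with an $O(L)$ site scan), the
probability-matrix method costs roughly constant work per site. The selector
uses the rate-matrix method on a branch exactly when $L t$ is strictly below
a threshold: 2.226 for homogeneous/discrete-rate models and 17.307 for
continuous Gamma (where the probability-matrix method loses its per-branch
matrix reuse). Ties go to the probability-matrix side, and a homogeneous
model counts as a 1-category discrete model. The constants are measured
crossover points and therefore hardware-dependent; `calibrate_switching()`
re-measures them on the host (binary search for the cost crossover per
sequence length, then a least-squares fit of the crossover against $1/L$
through the origin) but only reports — it never silently overrides the
defaults.

## The indel process

Indel lengths live on $\{1, 2, \dots\}$: geometric and negative binomial
(shifted to support $\ge 1$), and Zipfian ($\Pr(k) \propto k^{-a}$) and
Lavalette ($\Pr(k) \propto ((k\,m)/(m-k+1))^{-a}$) truncated at a maximum
$m$. The default is Zipfian with exponent 1.7 truncated at 50 — the standard
empirical choice for real indel data. Zipfian/Lavalette are tabulated exactly
over their support; the unbounded geometric/negative-binomial samplers use an
inverse-CDF table truncated at the $1-10^{-12}$ quantile (total-variation
error below $10^{-12}$), while their means use the exact closed forms.

Two points in the event semantics are genuinely ambiguous and are resolved as
follows:

* **Insertion slots.** An insertion chooses uniformly among the $L+1$ slots
  around the $L$ non-gap residues (consistent with $I = r_I(L+1)$, which
  prices the append slot like any other). The new residues are placed
  immediately *before* the chosen non-gap residue — i.e. at the right
  boundary of any intervening gap block — and slot $L+1$ appends at the very
  end of the row.
* **Deletions at the sequence end.** The rate $D = r_D(L - 1 + u_D)$ prices
  deletions that overlap the end of the sequence. msasim therefore draws the
  start uniformly among all $L$ non-gap positions and truncates the deletion
  when fewer than $j$ non-gap positions remain. A start range restricted to
  $L - j + 1$ positions would contradict the rate formula; the truncation
  reading reconciles the two.

A sequence that becomes all gaps ends its branch immediately, and all its
descendants inherit the all-gap row.

## Trees

`parse_newick()` accepts rooted and trifurcating-root Newick with
multifurcations (parsing is delegated to ape, with extra validation);
simulation runs from the root as given — no arbitrary rooting is inserted.
Zero-length branches are legal and copy the parent sequence.

Random topologies come from two generators. Yule-Harding grows a bifurcating
tree by repeatedly splitting a uniformly chosen extant lineage until $n$ tips
exist, then labels tips `T1..Tn` in random order (the model itself only
specifies the distribution over shapes; uniform lineage splitting is the
standard construction realizing it). Birth-death runs forward in time with
per-lineage speciation rate $\lambda$ and extinction rate $\mu < \lambda$,
restarts whenever the process dies out before reaching $n$ surviving
lineages, prunes extinct lineages and collapses the resulting degree-two
nodes. Tip-count conditioning (rather than age conditioning) was chosen to
mirror the Yule-Harding interface; simple rejection was preferred over
conditioned samplers because correctness is easy to see and desk-scale
performance is ample. Branch lengths are drawn i.i.d. from an exponential
with mean 0.1 substitutions/site by default, or from a user list.

## Traversal, memory and assembly

The tree is traversed depth-first (with an explicit stack, so caterpillar
trees of any depth work). An internal node's sequence is freed once all its
children are simulated; without indels each tip row can be streamed to the
output sink and freed immediately. The peak number of concurrently stored
sequences is then bounded by the tree depth — $\log_2(n) + 1$ for a balanced
bifurcating tree, $n$ in the caterpillar worst case — instead of the $2n-1$
a naive simulator stores. The instrumented peak is reported in every
simulation summary, and the bound is asserted in the tests.

Insertions at one node open a gap column in every other row. The default
assembler records a global chronological log of insertion events
`(column, length)` and patches rows lazily: a parent copy is brought up to
date when a branch starts, and every buffered row is patched once at the end.
The `naive` assembler physically inserts the gap block into every stored row
the moment the event happens. Both consume identical random streams and are
byte-identical on output — asserted over 100 random indel instances — so the
lazy assembler is a pure optimization, not a second semantics. With indels
enabled, streaming is disabled (later insertions retroactively add columns to
finished rows) and ancestral-sequence output is only available with streaming
off.

Randomness is organized as one user seed from which a substream seed is
derived for every (replicate, node) pair, so results do not depend on
traversal order and identical configurations reproduce byte-identical files.

## What the synthetic world does and does not establish

All test inputs are generated in code; the stated defaults are fixed once:
exponential branch lengths with mean 0.1, Zipfian(1.7, 50) indel lengths,
insertion/deletion rates 0.03/0.09 where an indel benchmark setting is
needed, and GTR + 0.2 invariant sites + Gamma shape 0.5 as the benchmark
heterogeneity model. Within that world the suite establishes: exact
normalization, agreement of the two exponentiation paths, agreement of the
two branch algorithms (chi-square homogeneity across a
model × heterogeneity × branch-length battery), Poisson event counts at the
analytic rate, first-order indel rates, the depth bound on memory, and
byte-level determinism. It does not establish biological realism of the
defaults, performance at the scale of millions of sequences, or the
hardware-specific optimality of the switching constants (only their values
and the flip behaviour are contracted).

## Known limitations

Mixture, partition, codon and branch-specific models are out of scope, as is
inferring a model/tree from an empirical alignment to mimic it. Indel rates
are site-homogeneous. The simulator is single-threaded by design. Trees with
very large branch lengths under the Gillespie method cost $O(L^2 t)$; the
adaptive selector exists precisely to route such branches to the
probability-matrix method.
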