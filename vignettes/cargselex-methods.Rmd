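---
title: "Methods: SELEX-seq inference of CArG-box binding specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SELEX-seq inference of CArG-box binding specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cargselex` analyzes SELEX-seq experiments that probe the DNA-binding
specificity of MADS-domain transcription factors, which bind as dimers to
10-bp CArG-box elements (SRF-type consensus CC(A/T)~6~GG, often with an
A-tract center A^n^T^m^, n+m ≥ 4). The package covers the whole inference
chain — background modelling of the initial library, motif-length selection,
relative k-mer affinities, PWM discovery, flank preferences, intra-motif
dependence, and motif divergence — together with a SELEX simulator that
plants a CArG-box-shaped binding model, so every stage can be exercised and
validated end to end without external data. The numbered scripts under
`analysis/` run the full workflow on simulated libraries and write all
tables under `results/`.

# The simulator

## Probe layout

Probes are 99 nt: a 5' adapter (33 nt, ending in the dinucleotide CT), a
25-nt randomized variable region (near-uniform base composition, 25% each),
a 4-nt library barcode, and a 37-nt 3' adapter. The default adapters are
synthetic placeholders with the correct lengths and the CT terminus; real
adapter sequences can be injected through `probe_design()`. The CT terminus
matters: windows straddling the 5' boundary can use the adapter's CT as a
partial motif border, which is what produces the characteristic position
bias of "incomplete" CArG-boxes toward read offsets 1–2.

## Binding model and selection rounds

A `binding_model` scores every 10-nt window of a probe (including adapter
and barcode context) on both strands with per-position base energies plus
optional flank bonuses just outside the core; the probe weight is the
nonspecific baseline ε plus the Boltzmann sum over windows. The sum (rather
than a max) makes the target of the `(obs/exp)^(1/r)` affinity estimator
analytically predictable (`planted_affinity()`). The adapter-CT artifact is
modelled explicitly: the window whose first two bases are the 5' adapter's
terminal CT gets a reduced position-2 cost (`boundary_ct`), so partial
sites at the very start of the variable region are selected — an in-read
tolerance for CT would instead scatter such sites across all offsets and
erase the 5' concentration the probe layout actually produces.

Each selection round resamples the molecule population from the previous
round with probability proportional to weight, optionally multiplied by a
smooth GC-content PCR factor `exp(γ(GC − 0.5))`; a configurable fraction of
positive-control contaminant is spiked in after selection, mimicking
carry-over. The population size (`library_size`) is distinct from the
number of sequenced reads (`n_reads`): a real SELEX library holds many
orders of magnitude more molecules than are ever sequenced, and the
separation matters at desk scale because a fully read-limited library
(the default, `library_size = n_reads`) concentrates selection onto few
duplicated probes.

## Presets and their calibration

The `wt` preset encodes an SRF-type CArG-box with an A-preferring but
tolerant center (minimum-energy sequence CCAAAAATGG), flank bonuses for TT
upstream and AA downstream, and a `boundary_ct` term letting the adapter's
terminal CT act as a reduced-cost 5' border. The center penalties are
shaped so that the A-tract preference is decisive: a lone mid-core T (which
breaks the A-run without forming an A-tract) is expensive, so every
top-ranked CArG-box carries an A-tract while W-substitutions adjacent to
the terminal T stay cheap. The `mutant` preset shortens the A/T core and
makes the border positions S-tolerant (CCSAAAASGG-like); the
`single_target` preset prefers exactly one 10-mer and is used for
stringent-selection checks. No quantitative selection stringency is
available to emulate, so preset energies, β and ε are calibrated once so
that the planted structure is recoverable at the desk scales the package
uses (10^4^–10^5^ reads per round): strong enough that round-2 pools carry a
clear motif signal, weak enough that the finite library is not collapsed
onto a handful of probes. One layout detail is deliberate: the default
scanning barcode is ACTG (probe 4), because a G-initial barcode would let
the motif's final G be supplied by the constant region and every selected
read would then carry only 9 of the 10 motif bases — confounding width
selection with probe layout.

## What the simulator does not emulate

Dimer cooperativity, DNA-shape energetics, gel-separation efficiency and
sequencing error are out of scope. Passing recovery tests on simulated data
therefore shows that the estimators invert the generative model they assume,
not that real libraries satisfy that model; on real data the background can
be more structured (the order-selection step exists precisely for that) and
selection stringency is unknown.

# Background model and order selection

`fit_markov()` estimates an order-m Markov model from all read positions of
the forward reads (strands are not pooled), with additive pseudocount
α = 0.5 — at order ≥ 4 on desk-scale pools, many contexts would otherwise
have zero counts. Window probabilities chain a stationary-style m-mer
marginal (estimated from all read positions) with the conditionals; at read
length 25 the inhomogeneous end effects this ignores are negligible.
`select_order()` scores each candidate order by how well a model trained on
one R0 replicate predicts the other replicate's 8-mer counts (R² over all
4^8^ 8-mers, both directions averaged) and returns the smallest order within
0.001 of the best R² — near-ties between adjacent orders are the norm, and
parsimony resolves them deterministically. With a single R0 library the
pipeline falls back to split halves as pseudo-replicates.

# Motif length by information gain

The information gain of a selection round is the Kullback–Leibler divergence
(bits) of the round's k-mer distribution from the background model's, over
canonical k-mers (a k-mer and its reverse complement share a key; the
lexicographically smaller one is canonical). Two small-sample effects must
be handled at desk scale:

* **Duplicate probes.** Selection from a finite library (and PCR) resamples
  whole probes; after two rounds a sizable fraction of reads are exact
  copies. Copies add about two bits per extra base to the plug-in KL at
  k beyond the true width — pure library-bottleneck signal, carrying no
  information about binding-site width. Reads are therefore
  duplicate-collapsed before counting (`dedup = TRUE`).
* **Support-size bias.** The plug-in KL estimator is biased upward by a term
  that grows with the number of k-mer categories; by k = 14 the category
  count exceeds the window count. `information_gain()` therefore subtracts
  the same statistic computed on equally sized blocks of (duplicate-
  collapsed) R0 reads — a matched baseline with the identical sampling bias,
  so the net value isolates the divergence created by selection. Up to
  three disjoint R0 blocks are averaged to reduce baseline noise.

`select_k()` applies a plateau-onset rule: the smallest k whose gain reaches
99% of the maximum (`plateau_tol = 0.01`). The underlying divergence is
non-decreasing under refinement, so "maximal" is read as the onset of
saturation; on simulated wildtype libraries the net profile rises to the
planted width of 10 and falls off beyond it.

# Relative affinities

For each canonical k-mer observed in round r, the raw enrichment is
`(observed / expected)^(1/r)` with expectations from the R0 background;
affinities are raw values normalized so the strongest k-mer is exactly 1.
Affinities are invariant to scaling all counts and to query orientation.

K-mers are kept but flagged `low_confidence` (never silently removed,
preserving auditability) in three situations: fewer than 5 window counts;
fewer than 5 distinct read sequences supporting the count; or more than
half the count contributed by a single read sequence. The last two flags
are the desk-scale counterpart of the count floor: selection from a finite
library resamples whole probes, so a strongly selected probe reaches
hundreds of copies after two rounds and every one of its windows — fifteen
of which are incidental background — inherits that copy number. A count
that is really one probe's copy number measures sampling luck, not binding.

The simulator's `planted_affinity()` supplies the analytic target these
estimates converge to: a read containing k-mer w is selected over r rounds
with probability proportional to weight^r, so the target is
`E[weight^r | contains w]^(1/r)` over the random context around w,
evaluated in closed form (for r = 2 via the second moment over all ordered
pairs of overlapping windows). The round-aware form matters because k-mers
that merely overlap a strong site ("hitchhikers") have skewed conditional
weight distributions.

`loess_combine()` integrates the low-bias R1 estimate with the low-variance
R2 estimate by locally weighted linear regression (tricube weights,
degree 1, span 0.5) of log affinities — enrichment is multiplicative across
rounds, so the log scale is the right one. The fit is exact local
regression at every point for up to 2000 shared k-mers; above that, exact
fits at 256 quantile anchors are interpolated linearly, which is transparent
for the smooth monotone relations this step sees. The combined estimate is
back-transformed and renormalized to maximum 1.

# Motif discovery

Training sequences are the k-mers with affinity > 0.4 (flagged
low-confidence k-mers excluded by default — duplication artifacts would
otherwise enter the motif), padded with k/2 N's on each side (length 2k)
and weighted by 10³ × affinity (real-valued). The cutoff aims at a workable
training set (on the order of 50–200 sequences) while keeping the motif
informative. `discover_pwm()` runs
one-occurrence-per-sequence (OOPS) EM over all windows × both strands with a
uniform position/strand prior and uniform 0.25 background. N positions are
marginalized — emission factor 1 under both motif and background — keeping
likelihoods comparable across sequences with different N counts; OOPS
rather than a zero-or-one model because each training sequence is built
around exactly one site. EM stops at a weighted log-likelihood gain below
10⁻⁶ per unit total weight or 500 iterations; the best of `restarts`
initializations wins (default 200, seeded; half are random Dirichlet draws
and half are softened data windows, most informative first, which anchors
the search at the padded k-mers themselves; ties broken by the
lexicographically smallest consensus), and the final matrix gets a
pseudocount of 0.5 per cell. The output orientation is canonicalized so the
consensus shows CC before GG when applicable, with the lexicographically
smaller consensus as tie-break (the reverse complement of a CArG-like motif
also reads CC-before-GG). The IUPAC consensus calls a single base when its
probability is
≥ 0.5 and at least twice the runner-up, a two-letter code when the top two
sum to ≥ 0.75, and N otherwise.

`flank_extract_orient()` performs the guided flank analysis: every 18-nt
window of the distinct read sequences whose center matches CC(A/T)₆GG (on
either strand; the pattern is closed under reverse complement) is
extracted, weighted by log2(1 + copy number) — enrichment counts as
evidence, but a single duplicated probe cannot dominate the columns — and
the residual two-fold orientation ambiguity of the W-palindromic core is
resolved by a two-orientation mixture EM over all 18 columns. The global orientation of
the result is fixed by the lexicographically smaller consensus, so flank
preferences (TTN upstream, NAA downstream, in one orientation or its mirror)
are read off columns 1–4 and 15–18. `position_bias()` tabulates exact
forward-strand matches of given k-mers per read offset and classifies each
k-mer as a complete CArG-box (CC(A/T)₆GG), incomplete ((A/T)₂N₆(A/T)₂ but
not complete), or other.

# Intra-motif dependence and complexity

`fit_dependence()` factorizes the aligned motif left to right: each
position's distribution is conditioned on a parent set of preceding
positions. Proximal models fix parents to the d adjacent predecessors;
distal models search all parent subsets of size ≤ d, scored by the
BIC-penalized weighted log-likelihood (`logL − free/2 · log(Neff)`, with
Kish's effective sample size for weighted data). Conditionals are
pseudocount-smoothed weighted ML estimates. Optional context-tree merging
chooses, per parent level, among the 15 set partitions of {A,C,G,T} by
dynamic programming under BIC, pooling parent symbols that behave alike.

The intra-motif complexity (IMC) of a fitted model is the weighted mean
per-sequence log₂-likelihood gain over the mononucleotide (PWM) model
fitted on the same data with the same smoothing — bits of statistical
dependence the representation captures beyond independent columns. The PWM
itself has IMC exactly 0, and with unpenalized ML fits the nestedness
ordering holds on any dataset: 0 ≤ proximal₁ ≤ proximal₂, and
proximal_d ≤ distal_d ≤ distal_{d+1}. BIC-penalized fits may order
differently (the structure is chosen for parsimony, not fit), so nestedness
checks use unpenalized fits.

# Motif comparison

`pwm_jsd()` computes the per-position Jensen–Shannon divergence with log
base 2 (each position in [0, 1] bits) and aggregates by sum over positions
(default) or mean; both conventions are exposed because aggregate values
over a 10-column motif are interpretable either way. Because discovery
strand is arbitrary, the reverse complement of the second motif is also
evaluated by default and the orientation minimizing the aggregate is
reported. `difference_logo()` emits the numeric difference-logo table:
stack height per position is the JSD, and each letter's signed height is
`JSD · (p(a) − q(a)) / Σ_b |p(b) − q(b)|` (positive = enriched in the first
motif), with identical columns yielding zero heights.

# CArG-box and A-tract tables

There are exactly 36 distinct SRF-type CArG-boxes modulo reverse complement
(64 W₆ centers, 8 of which give reverse-complement-palindromic boxes:
(64 − 8)/2 + 8). `enumerate_srf_cargboxes()` lists them canonically with
A-tract annotation; an A-tract is a substring A^n^T^m^ with n + m ≥ 4 —
pure A- or T-runs qualify, and the definition is strand invariant.
`atract_affinity_table()` joins the 36 boxes with a run's affinities
(missing boxes get affinity 0 and a flag), and `top_affinity_report()`
emits the top-n table with CArG/A-tract annotation; all rankings break ties
lexicographically for determinism.

# Problem sizes and reproducibility

The analysis scripts use 5 × 10⁴ reads per round from 2 × 10⁵-molecule
libraries and 200 EM restarts. The test suite's main fixture uses 10⁵
reads from a 4 × 10⁵-molecule library; the motif-length check runs at the
fully read-limited 10⁵-read scale; and two properties use
mechanism-targeted model variants — the flank-preference check strengthens
the flank bonuses and the position-bias check strengthens the adapter-CT
boundary term — because at desk scale only a few hundred distinct
CArG-matching windows exist per run and the mild default effects would
drown in sampling noise. Passing these tests therefore shows that each
estimator inverts the mechanism it targets, at signal strengths where the
mechanism is identifiable. Every stochastic stage takes an explicit seed,
every output table records the seed and a config hash, and re-running with
the same configuration reproduces all tables byte for byte.

# Known limitations

* Fine-grained affinity ranks are noisy at desk scale: a specific 10-mer
  is carried by only a few source probes per 10⁵ × 25-nt reads, so two
  rounds of resampling leave ~10% relative error on affinity estimates
  while the spacing between adjacent top-100 k-mers is ~1%. Estimated
  values track the planted targets closely, but rank correlations near 1
  require read depths comparable to real experiments (~10⁷⁻⁸ reads).
* Relative affinities assume the enrichment-per-round model; saturation of
  strong binders across many rounds would bias later rounds (the default
  analysis round is R2).
* The matched-baseline information gain requires an R0 pool; without one,
  the plug-in value is returned and is only comparable across k at large
  read counts.
* Dependence-model search is exhaustive over parent subsets and is meant
  for motif-scale lengths (≤ ~20 positions), not long sequences.
* The EM uses a uniform background inside the discovery step; strongly
  biased initial libraries are handled upstream (affinities are
  background-corrected), not inside the EM.
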