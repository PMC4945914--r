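---
title: "Methods: estimator- and binarizer-dependence of EEG functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimator- and binarizer-dependence of EEG functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

A functional brain network is a graph whose nodes are EEG sensors and whose
edges encode statistical dependency between the sensors' time series. Two
methodological choices stand between a multichannel recording and a graph
metric: (i) the *dependency estimator* that turns two time series into a
connection weight, and (ii) the *binarization* rule that turns the weighted
all-to-all matrix into a 0/1 adjacency. Neither choice is canonical, and
group differences reported in the clinical literature (e.g. for Alzheimer's
disease) disagree across studies that differ mainly in these choices.

fconnet implements the full comparison grid — four estimators, four
binarizers, six graph metrics, pointwise Wilcoxon rank-sum group comparison
over binarizer parameter sweeps — together with a synthetic resting-EEG
cohort generator with known planted coupling, so the method-dependence of
network conclusions can be demonstrated and every component verified
against analytic anchors and brute-force oracles.

## Dependency estimators

All estimators operate on 1-second artifact-free epochs and are averaged
over epochs (the per-subject matrix is the epoch mean), except coherence,
which pools spectra across epochs (below).

**Pearson correlation.** Per epoch,
$r_{ij} = \mathrm{cov}(i,j)/\sqrt{\mathrm{var}(i)\,\mathrm{var}(j)}$, and
the stored weight is $|r_{ij}|$. The absolute value is a deliberate
convention: threshold, density, MST and MCC binarization all assume weights
that order from "weak" to "strong", which signed correlations do not. A
`mode = "positive"` switch clips negative correlations to zero instead.

**Coherence.**
$C_{ij}(f) = |G_{ij}(f)|^2 / \big(G_{ii}(f)\,G_{jj}(f)\big)$, averaged over
all FFT bins whose center lies in the analysis band (7–13 Hz inclusive by
default). A single-segment coherence estimate is identically 1, so spectra
are estimated per epoch with rectangular windows and pooled across epochs
before the ratio is formed; the epochs act as the realizations of a Welch
estimate. With $K$ independent epochs the null bias of this estimator is
approximately $1/K$, which the test suite verifies at $K = 60$.

**Phase order parameter.** Instantaneous phases come from the analytic
signal (FFT half-spectrum method); the pairwise index is
$P_{uv} = \big|\langle e^{i(\varphi_u(t) - \varphi_v(t))}\rangle_t\big| \in
[0, 1]$. Phase locking at any constant lag, including $\pi$, gives
$P = 1$; for $T$ independent uniform phases $E[P] = \sqrt{\pi}/(2\sqrt{T})$
(the mean resultant length of $T$ uniform unit vectors). Because Hilbert
phases are unreliable near epoch boundaries, the first and last 10% of
samples of each epoch are excluded from the average.

**Synchronization likelihood.** Both series are delay-embedded
($e = 10$ dimensions, lag $L = 10$ samples, so a 500-sample epoch yields
410 state vectors). Temporally close vector pairs are excluded by a Theiler
window; the stated correction $w = 0.1$ is dimensionally ambiguous in the
source literature, and we read it as a *fraction* — pairs with
$|t - s| \le \lceil 0.1 N \rceil$ are excluded — with a
`theiler_samples = TRUE` switch for the literal-samples reading. Per
channel a critical radius is calibrated so the correlation integral (the
fraction of admissible pairs closer than $r$, strict inequality, Euclidean
metric) equals $P_{\mathrm{ref}} = 0.01$; the radius is the
$P_{\mathrm{ref}}$-quantile of the sorted admissible distances, so the
round-trip error is below one pair count. The likelihood in direction
$i|j$ is the fraction of $j$-recurrent pairs that are also $i$-recurrent,
and the reported value is the arithmetic mean of the two directions (the
symmetrization is our choice; the defining property is that identical
channels give exactly 1 and independent channels give
$\approx P_{\mathrm{ref}}$, both of which are asserted in the tests).

## Binarization

* **Threshold** keeps edges with weight strictly greater than `th`; networks
  may be disconnected or empty, and edge counts differ across subjects.
* **Density** keeps the `round(kappa * N(N-1)/2)` strongest edges, giving
  every subject the same edge count. Ties at the cut are broken by
  descending weight, then lexicographic `(i, j)` — deterministic by
  construction.
* **MST** converts weights to distances `d = 1 - w` (strong dependencies
  become short distances; `1/w` available) and keeps the minimum spanning
  tree: exactly `N - 1` edges, acyclic. Taken literally, "minimizing the
  summation of link weights" on dependency weights would retain the weakest
  links; every practical use of MST on brain networks keeps the strongest,
  and so do we.
* **MCC** adds edges in descending weight order — including edges internal
  to an existing component — until the graph is connected; equal weights at
  the connecting step enter as a whole tie group. The result equals the
  threshold graph at the percolation-critical weight, always contains the
  MST edge set, and preserves strong local connections that MST discards.

Default sweep grids: `th` in 0.05–0.95 (step 0.05), `kappa` in 0.05–0.50
(step 0.05).

## Graph metrics

Global efficiency (mean inverse shortest-path length, `1/Inf = 0` for
disconnected pairs), node and edge betweenness (Brandes accumulation,
unnormalized, unordered pairs; endpoint pairs count for edges but not for
nodes — a path graph 1–2–3 gives edge (1,2) the value 2 and node 2 the
value 1), local efficiency (global efficiency of each node's
neighbor-induced subgraph; exactly 0 on every tree, hence on every MST
network), Newman–Girvan modularity (Q maximized by seeded agglomeration
alternated with Kernighan–Lin node-move passes — tentative moves may go
downhill, with the best intermediate partition kept — over 10 restarts,
the first using best-gain merges and the rest randomized positive-gain
merges for basin diversity; on graphs up to 8 nodes the optimizer attains
the exhaustively enumerated optimum in the test suite), and degree
assortativity (Pearson correlation
of edge-endpoint degrees, both orientations; `NA` with an explanatory
reason on degree-regular graphs, and such subjects are flagged rather than
silently dropped from group statistics).

Betweenness is left unnormalized because the rank-sum group comparison is
invariant to common scaling; the pair-counting convention above is fixed
and tested.

## Group statistics

At every grid point the two groups are compared with the two-sided Wilcoxon
rank-sum test (exact enumeration for combined n ≤ 12 without ties, normal
approximation with tie correction otherwise), significance at α = 0.05,
*without* multiple-testing correction across grid points — matching the
analysis convention of the sweep-figure literature this package mirrors; a
Benjamini–Hochberg option exists but is off by default. Testing is
pointwise per grid point, as per-point significance markers imply.

## The synthetic cohort generator

Real resting EEG is emulated as band-limited Gaussian oscillations plus
white sensor noise:

* every channel has an intrinsic alpha-band oscillator (exactly
  band-limited 7–13 Hz Gaussian noise, built in the frequency domain from
  complex Gaussian Fourier coefficients, so the band confinement is exact
  and phases are random per subject);
* each planted coupling edge `(i, j, s)` contributes a shared latent
  oscillator with mixing weight `sqrt(s)`, with the intrinsic oscillator
  scaled to keep unit signal variance; a single edge of strength `s`
  between noise-free channels therefore has population correlation exactly
  `s`, and noise-free `s = 1` makes the channels identical;
* defaults: 16 channels, 60 s at 500 Hz, oscillation RMS 15 uV, white
  noise SD 5 uV. The per-channel sum of incident couplings must not exceed
  1 (the unit variance budget), which the constructor enforces.

What the generator does **not** emulate: volume conduction and sensor
geometry, 1/f background spectra, non-Gaussian and nonstationary dynamics,
genuine nonlinear (generalized-synchronization) coupling, ocular/muscle
artifacts beyond rectangular test transients. Passing tests therefore
validate the *pipeline algebra* — estimator and binarizer implementations,
their analytic anchors, and the statistical machinery — not claims about
clinical EEG.

An important emergent feature the generator does share with short
narrowband recordings: a 1-second 7–13 Hz epoch has only about
$2 \cdot 6\,\mathrm{Hz} \cdot 1\,\mathrm{s} \approx 12$ effective samples,
so uncoupled channel pairs show a spurious mean `|r|` floor of roughly
0.8/sqrt(12) ≈ 0.23. Planted edges compete with this floor when networks
are binarized, which is exactly the regime in which method choice matters.

## The planted two-group studies

**Topology.** The default two-group cohort couples channels as a perfect
matching — (1,2), (3,4), ... at the group coupling scale — so "same
topology, weaker coupling" is taken literally: 14 subjects at scale 0.8
versus 16 at scale 0.4. Although the planted edge *ranks* are identical in
both groups, the binarized topologies differ systematically, through the
coupling-dependent common-average-reference residue and the
strength-dependent dispersion of per-epoch correlation estimates that rank
the non-planted edges. The package's power study verifies that global
efficiency under density binarization at the middle of the default grid
(κ = 0.25) separates the groups in at least 80% of 50 independent cohort
replicates. The direction of the difference (the weakly coupled group shows
*higher* global efficiency here) is a property of this generator and
referencing scheme, not a general law; the test asserts two-sided
significance.

**Problem sizes.** Power replicates use 30 epochs of 1 s per subject and
16 channels; the method-dependence grid uses 20 epochs with all four
estimators. These desk-scale sizes were fixed at design time from a pilot
of the generator (power was, if anything, higher at 30 than at 60 epochs,
because a noisier per-epoch rank ordering amplifies the topological
contrast between groups).

**Type-I calibration.** The rank-sum false-positive rate is calibrated on
one null cohort (both groups at scale 0.8): 2000 random label permutations
of its global-efficiency values must flag significance at a rate inside
[0.03, 0.07] at α = 0.05.

**Method dependence.** On one fixed seeded cohort in which group B has
globally weakened coupling *and* doubled sensor noise, the 4 × 4 grid of
(estimator × binarizer) significance flags for global efficiency is
non-constant: some cells flag a group difference and some do not. This is
the package's mechanical demonstration that network conclusions depend on
the analysis method even on identical data.

## Numerical choices and degenerate inputs

* Zero-phase filtering applies the squared magnitude response of a
  Hamming-window FIR design (forward–backward convolution) in the
  frequency domain, with zero padding at epoch edges. A literal
  "fifth-order FIR" cannot isolate a 6 Hz band at 500 Hz — five taps have
  essentially no frequency resolution there — so the default order is
  `2 * ceiling(fs / low)` (144 at 500 Hz / 7 Hz) and `order = 5` remains
  available for literal fidelity.
* The artifact "transition threshold" is applied to consecutive-sample
  differences (the simplest reading); an epoch-wise peak-to-peak option is
  provided. Rejection accumulates monotonically: lowering a threshold can
  only add masked epochs. If every epoch is rejected the package raises an
  explicit "no clean epochs" error rather than returning an empty average.
* Degenerate connectivity inputs fail loudly and specifically:
  zero-variance channels (correlation), constant series (Hilbert phase),
  series shorter than the embedding span, empty Theiler-admissible pair
  sets, and `p_ref` below the pair-count resolution (warning, smallest
  nonzero distance used).
* Disconnected weighted graphs are an error for MST/MCC at binarization
  time; within sweeps such failures are recorded as missing values with
  the error message as the reason, so group comparisons are never silently
  based on fewer subjects than reported.
* All tie-breaks (density cut, MCC tie groups, modularity restarts) are
  deterministic under a fixed seed; the full pipeline run twice with one
  configuration produces byte-identical report JSON.

## Known limitations

The generator's linear common-drive coupling cannot probe what
synchronization likelihood is uniquely sensitive to (nonlinear generalized
synchronization); SL is validated here against its analytic anchors and a
brute-force oracle instead. Coherence windowing is rectangular (no taper),
matching the pooled-periodogram description; tapering would change
absolute values slightly but not the comparisons. The surface-Laplacian /
current-source-density transform used by some EEG pipelines is out of
scope; common-average referencing is the only spatial filter offered.
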