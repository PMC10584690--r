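---
title: "Decoding single-molecule chromatin fiber accessibility: models and methods"
author: "chromfiber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding single-molecule chromatin fiber accessibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromfiber)
```

# Scope

`chromfiber` implements the downstream computational stack of single-molecule
chromatin accessibility footprinting on long reads: a nonspecific adenine
methyltransferase (e.g. EcoGII) marks accessible DNA with m6dA, polymerase
kinetics (interpulse durations, IPD) reveal which adenines were methylated,
and unmethylated stretches are protein footprints. The package starts from
per-adenine evidence — binary methylation calls, or log-IPD residuals plus
matched controls — and provides:

* a two-state chain hidden Markov model (HMM) that decodes molecule-wide
  accessibility by Viterbi;
* footprint calling, per-region nucleosome counting and per-fiber density;
* single-molecule autocorrelograms, repeat-length (NRL) peak estimation,
  per-density averaging, Leiden clustering and UMAP embedding;
* a Monte-Carlo simulator of nucleosome arrays remodeled in silico by a
  "clamping" (fixed-ruler) or a "length-sensing" (flank-gated) process;
* enrichment statistics: Fisher's exact cluster-by-domain tests with Storey
  q-values, differential odds-ratio matrices, PCA against per-domain
  density, log-odds density enrichment, and weighted interval scheduling for
  overlapping repeat matches;
* a seeded synthetic-data generator so that every stage is testable without
  sequencing data.

Upstream steps (basecalling, CCS, alignment, IPD extraction, neural-network
IPD prediction) are out of scope; the package consumes their outputs.

# The accessibility HMM

For each molecule we observe binary methylation calls at the usable adenines
of a template. The hidden state at each adenine is *accessible* or
*inaccessible*. Emissions are Bernoulli with per-adenine probabilities: in
the accessible state, the fraction of positive-control molecules (fully
methylated naked DNA) called methylated at that adenine; in the inaccessible
state, the fraction of negative-control (unmethylated) molecules called
methylated. Observed control fractions are smoothed as

$$ p = \frac{k + 0.5}{n + 0.5} $$

so no probability is exactly zero (`emissions_from_controls()`). A
saturated positive control legitimately yields $p = 1$; an optional epsilon
cap exists but is off by default. In "genomic" use, where controls cannot be
tallied per position, per-adenine rate maps are supplied directly.

Transitions encode persistence of state over distance. For an expected
state run length of $L$ bp, the per-base switching probability is $1/L$
(geometric), so the probability of remaining in the same state across an
inter-adenine gap of $B$ bases is

$$ P(\text{stay}) = \left(1 - \tfrac{1}{L}\right)^B. $$

The default $L = 1000$ bp is deliberately much longer than a nucleosome:
switching then requires a real burden of evidence, which suppresses spurious
state flips (`viterbi_decode()` has a regression test showing the number of
decoded switches is non-increasing in $L$). The initial state is accessible
with probability 0.5. Decoding is exact Viterbi in log space, linear in the
number of adenines; `brute_force_decode()` enumerates all $2^n$ paths on
small instances as an independent oracle. Exact ties are broken toward the
inaccessible state — conservative footprint calling; ties are asserted on
probability, not path, in the tests.

Uncalled or unusable adenines are simply skipped; their distances are
absorbed into $B$. The decoded path (accessible = 1, inaccessible = 0) is
interpolated to a per-base track: linear interpolation between decoded
adenines by default (`"nearest"` is available as an option), constant
extrapolation beyond the first and last decoded adenine. Linear was chosen
because it makes the 0.5-crossing fall halfway between opposite-state
adenines, which is the symmetric, least-committal boundary estimate.

# Footprints, counts and density

Inaccessible regions are maximal runs of track values at or below 0.5
(inclusive, exactly as the threshold is stated). Region lengths are mapped
to nucleosome counts by a threshold ladder: the default — below 100 bp
subnucleosomal (0), below 280 bp one nucleosome, below 450 bp two, below
620 bp three, then one more per 170 bp — is a documented heuristic built
from the 147-bp nucleosome core and typical mono-nucleosome footprint
lengths (~120–160 nt). On real data these cutoffs should be calibrated on
the region-length histogram; `suggest_nuc_cutoffs()` proposes valleys of a
kernel density estimate as candidate boundaries, and the ladder is fully
configurable. Per-fiber density is total nucleosomes × 1000 / template
length (nucleosomes per kbp); `horizon_histogram()` bins (midpoint, length)
pairs for horizon-plot views.

# Fiber architecture statistics

The autocorrelogram of a per-base track,
$r(k) = \sum_t (x_t-\bar x)(x_{t+k}-\bar x) / \sum_t (x_t-\bar x)^2$
(computed via `stats::acf`, which implements exactly this normalized,
mean-centered estimator), measures spacing regularity: for a regular array
its first in-window peak sits at the repeat length. `find_peak()` returns
the in-window argmax that is also a local maximum (plateau ties take the
smaller lag; a monotone decay has no peak). The default search window,
100–500 bp, covers NRLs observed in vivo (~172–357 bp). Per-molecule peaks
should be read as *average internucleosomal distance*; they are NRL
estimates only after averaging or clustering, so `per_density_profiles()`
averages autocorrelograms within density groups before peak calling.

Clustering follows the scanpy-style recipe: a k-nearest-neighbor graph
(Euclidean distance on autocorrelogram vectors) with Leiden community
detection (modularity objective, resolution 0.4), then removal of the
smallest clusters while their cumulative share stays below 5% of molecules.
One deliberate design choice: the neighbor count defaults to
`max(15, min(100, n/8))` rather than a fixed 15. On desk-scale datasets
(hundreds of molecules) a sparse fixed-k graph lets the modularity
objective fragment a single homogeneous fiber population into several pure
sub-communities along incidental low-dimensional continua (array offset,
nucleosome count); we verified this for unweighted kNN, shared-neighbor
Jaccard, Gaussian-kernel and UMAP fuzzy graphs alike. A neighborhood that
grows with the dataset keeps genuine populations intact while still
separating distinct array types; `k` remains a user-facing argument.
`umap_embed()` (via `uwot`, single-threaded, seeded) is for visualization
only — no statistic is computed from the embedding.

# The array simulator and the two remodeling processes

`place_nucleosomes()` builds random arrays by random sequential adsorption:
uniform candidate entries accepted only if the 147-bp footprint overlaps
nothing and every internal linker is at least 10 nt (an initialization
constraint only). Because nothing is ever removed, packing obeys the Rényi
jamming limit — near-saturating densities (≥ 13 nucleosomes on a 2,712-bp
template) can jam, which raises an error after a configurable number of
consecutive rejections. `simulate_fiber_ensemble()` redraws a jammed fiber
from a fresh substream (bounded retries) so near-limit densities can still
be sampled.

Two in-silico remodeling processes act on these arrays:

**Clamping ("ruler").** One 5′→3′ pass over adjacent pairs. A 3′ nucleosome
is *visible* if the current linker (exit-to-entry gap) is at most the
visibility threshold (183 nt); a visible nucleosome is slid against its 5′
neighbor — the barrier — to a linker of $d \sim \mathcal N(\text{ruler},
\sigma)$ truncated at zero (σ = 0 by default, i.e. a deterministic ruler).
Exits update as the pass proceeds. The visibility threshold is applied to
the *linker* rather than the entry-to-entry distance: only this reading
lets clamping act at low densities, where fixed per-density peaks are the
process's defining signature. Slid nucleosomes are kept on the template and
never pushed into their 3′ neighbor.

**Length-sensing.** The remodeler senses extranucleosomal DNA on both
sides and only slides toward a flank of at least the sensing cutoff (20 or
48 nt are the biologically motivated values); with both flanks sufficient
the direction is a fair coin flip, and flanks at the array ends are
measured to the template boundaries. Nucleosomes are visited 5′→3′ within
each of `n_sweeps` sweeps, moving `step` nt per visit (defaults: step 1,
500 sweeps; an `until_blocked` option slides until the chosen flank is
exhausted instead). Termination is by sweep count, not convergence — the
random direction choice yields a fluctuating steady state, not a fixed
point. Since the cutoff never falls below the step, no move can create an
overlap, and both processes conserve nucleosome count exactly (sliding
only, never eviction or loading).

The two processes leave opposite fingerprints in per-density averaged
autocorrelograms on 2,712-bp templates: clamping pins the peak at
nucleosome + ruler (147 + 20 = 167 bp) across densities 5–12, while
length-sensing peaks decrease strictly with density (Pearson r ≤ −0.99 in
our reference runs). The sign of the peak–density slope therefore
classifies the generating process — the package's central scientific
check. Post-remodeling linkers may drop below the 10-nt initialization
minimum; only non-negativity is enforced after remodeling. The simulator
deliberately omits sequence-dependent positioning energies, eviction and
loading, and continuous kinetic discrimination of flank length (the gate is
a step function).

# The mixture-threshold stage

Methylation calls derive from per-adenine log-IPD residuals: a large
positive residual (slower kinetics than the sequence context predicts) is
evidence of m6dA. Per adenine, a two-component Student's-t mixture is fit
to control-derived residuals by ECM (latent-gamma E-step; weighted
location/scale M-step; degrees of freedom by solving the digamma equation,
bounded below at 1, or held fixed), to a log-likelihood tolerance of 1e-6.
The methylation cutoff is the point between the component means where a
residual is equally likely under either component. "Equally likely" is
read as equal *weighted* component densities — posterior responsibility ½,
the standard mixture-model reading; the unweighted variant is available
via `weighted = FALSE`. Calls use a strict `>` at the cutoff (boundary
ties unmethylated).

An adenine's predictions are used downstream only if (1) at least one
component mean is positive, (2) the mean gap is at least a configurable
threshold (default 0.2, the midpoint of the conventional 0.1–0.3 range;
chosen per amplicon in practice), and (3) at least 2% of training
residuals exceed the cutoff. These filters are deliberately lenient — the
HMM's control-derived emissions already down-weight uninformative
adenines.

# Enrichment statistics

`fisher_enrichment()` tests each (cluster, domain) cell of a molecule
cross-tabulation with the two-sided exact test (the standard rule: sum of
table probabilities at most the observed one), reporting the sample odds
ratio ad/bc with infinities preserved and empty-margin cells flagged
rather than dropped. All tests in one call are corrected as a single
family with `storey_qvalues()`, a from-scratch implementation of the
Storey procedure (λ grid 0.05–0.95 in steps of 0.05, cubic
smoothing-spline smoother for π₀, clamped to (0, 1]); families smaller
than 100 tests fall back to π₀ = 1, where the q-values coincide exactly
with Benjamini–Hochberg — an identity the test suite asserts.
Significance is called at q < 0.05.

`differential_matrix()` subtracts matched odds-ratio matrices elementwise
(raw subtraction as printed; a log-odds option exists, and infinite cells
propagate rather than being imputed — mask them before PCA).
`pca_density_correlation()` treats domains as observations, centers
columns, keeps up to four components and correlates PC1 scores with
per-domain mean nucleosome density (Pearson and Spearman, two-sided).
`log_odds_density_enrichment()` compares binned cluster-specific and
background density distributions with additive smoothing so all log-odds
are finite. `weighted_interval_schedule()` resolves overlapping BLAST
repeat matches by exact dynamic programming over half-open intervals
(sort by end, binary-search predecessors, O(n log n)), maximizing the
summed bitscore — exact for the given scores, verified against exhaustive
subset search; `read_blast_tab()` converts outfmt-6 rows (1-based,
inclusive, possibly reversed) to 0-based half-open scored intervals.

# The synthetic-data generator

`make_rate_map()` emulates sequence-context variability of methyltransferase
efficiency: adenine positions by independent inclusion at fraction 0.5 (an
A·T pair has its adenine on exactly one strand, and both strands are
collapsed onto one coordinate track, so at most one adenine per position),
and per-adenine Beta-distributed call probabilities — mean 0.40 when
accessible, mean 0.02 when inaccessible. These are fixture defaults chosen
to make 147-bp footprints detectable at realistic evidence levels, not
measured constants. `simulate_molecule()` is the HMM's exact generative
model (Bernoulli calls conditioned on planted footprints);
`simulate_controls()` produces positive/negative control molecules;
`simulate_residuals()` draws labelled two-component t samples for the
mixture stage. Everything is seed-deterministic.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: polymerase kinetic noise and its sequence
dependence (residuals are drawn from the assumed mixture, not from
kinetics), mappability and coverage variation, chimeric or partial
molecules, sequence-programmed nucleosome positioning, and any mismatch
between the HMM's emission model and reality. Synthetic tests validate the
inference machinery, not the biology.

# Numerical and design notes

* Coordinates are 0-based, half-open everywhere; templates default to the
  2,712-bp scale of the reference amplicon.
* All stochastic operations take a `seed` argument; `run_workflow()`
  derives independent per-stage substreams from one master seed, so no two
  stages share random state.
* Viterbi works entirely in log space; emission probabilities of exactly 1
  are kept (log1p-based complements keep 0-probability branches at -Inf,
  which the max handles correctly).
* EM non-convergence within `max_iter` warns and returns the best estimate
  flagged via `attr(, "converged")`.
* `equal_likelihood_cutoff()` root-finds between the component means and
  raises if no root lies in the bracket (possible for extreme weight
  ratios; a wider bracket can be supplied).
* Degenerate inputs raise informative errors: constant tracks in
  `autocorrelogram()` (undefined normalization), identical residuals in
  `fit_t_mixture()`, empty state paths in `interpolate_track()`. Constant
  peak vectors in `density_peak_correlation()` return r = 0, p = 1 by
  convention.
* Decoded-boundary precision is limited by information, not implementation:
  the decoder cannot place a footprint edge more precisely than the nearest
  methylated accessible adenine, which sits a Geometric(p_acc) number of
  adenines from the true edge. At p_acc ≈ 0.4 roughly half of planted
  boundaries fall within one local inter-adenine gap (median error ~3 bp);
  in the noiseless limit recovery is exact up to inter-adenine resolution.

# Problem sizes used in the reference analyses

The packaged analyses run at desk scale, chosen to make every check
reproducible in minutes on one core: 600 fibers per density for the
clamp/length-sensing comparison (densities 5–12; peak estimates stable to
~2 bp at this ensemble size), 200 molecules for decoding recovery, 20,000
residuals for mixture recovery, 200 molecules per planted population for
clustering, and 100–200 random instances per combinatorial oracle.

# Known limitations

* The remodeling simulator is a caricature: ordered 5′→3′ visits, discrete
  steps, a hard sensing gate, no kinetics. It is meant to generate
  discriminable expectations, not mechanistic predictions.
* Leiden cluster counts depend on graph construction; the scaling default
  documented above is calibrated for hundreds-to-thousands of molecules.
* The nucleosome-count ladder is heuristic and should be recalibrated per
  dataset.
* Storey π₀ estimation needs a reasonably large p-value family; small
  families deliberately reduce to BH.
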