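---
title: "Modelling Polycomb/Trithorax chromatin: states, rules and the bistability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Polycomb/Trithorax chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromsim)
```

## The model and its assumptions

`chromsim` simulates an array of *N* half-nucleosomes, each carrying a
combination of four histone modifications central to Polycomb/Trithorax
regulation: the silent marks H3K27me3 (written by PRC2, erased by UTX) and
H2A K118/119 monoubiquitination (PRC1 / PR-DUB), and the active marks
H3K27ac (CBP / NuRD) and a fused H3K4/36 methylation species (TRXG writers /
KDM erasers). Acetylation and trimethylation of K27 are mutually exclusive on
one tail, so a half-nucleosome occupies one of 3 × 2 × 2 = 12 states;
adjacent states differ by exactly one modification. Halves 2*k* − 1 and 2*k*
form whole nucleosome *k* (so *N* = 20 halves ≈ 10 nucleosomes ≈ 2 kb), and
the 144 ordered whole-nucleosome states are classified by their silent-mark
share into six categories (active-only, three bivalent grades, silent-only,
unmodified). Exhaustive enumeration gives the 15/15/1/113 partition that the
test suite verifies against an independently coded classifier.

Deliberate simplifications, inherited from the modelling literature this
package operates in: no mono/di/tri methylation degrees, no separate H3K4 vs
H3K36 species, no transcription or polymerase coupling, and no spatial
structure — every half interacts with every other half with equal
probability, justified for domains of a few kilobases.

### Moves

Each update draws four independent exponential waiting times, in a fixed
order (recruitment, beta, direct NURD, direct PR-DUB), and executes the
channel with the smallest increment; raw time advances by that minimum
*even when the attempted move fails*, reproducing the published update
scheme exactly (it is statistically equivalent to a standard
competing-exponentials simulation, but we keep the literal form so that
fixed-seed trajectories are auditable against the description).

* **Recruitment** (total rate 1 per array): a uniformly chosen half recruits
  one of the complexes its state allows (state 8 recruits nothing), with
  equal weight; a target is chosen uniformly among the *other* N − 1 halves;
  the complex's unique action is applied if the target admits it.
  Inhibitions are encoded twice, as in the biochemistry: at the recruiter
  (H2Aub-bearing states do not recruit bare TRXG; K4/36me-bearing states do
  not recruit catalytically active PRC2; PRC1-recruiting states do not
  recruit CBP) and at the target (TRXG cannot write onto H2Aub; PRC2 cannot
  methylate a K4/36me- or K27ac-bearing tail). The symmetric/asymmetric PRC2
  rule — a nucleosome methylated at K4/36 on *both* tails is refractory to
  K27 methylation, one modified tail is not — emerges from the per-half rule
  and is tested as such.
* **Beta** (default 0.1): recruitment-independent conversions (non-specific
  DNA binding, turnover, remodelling). One site of one half toggles; an
  unmodified K27 gains ac or me3 with equal probability. The coin
  orientation (u < 0.5 → ac) is arbitrary and frozen for reproducibility.
  Five transitions (gaining K4/36me on ubiquitinated halves; gaining K27me3
  on K4/36me halves) are reachable *only* through this channel.
* **Direct NURD / PR-DUB** (defaults 1.0 and 0.15): recruitment-independent
  removal of K27ac / H2Aub from a random half.
* **Replication** (optional): when accumulated raw time crosses
  generation_time × N (default 20 × N, i.e. every 20 plotted units), each
  half is independently reset to the unmodified state with probability 0.5.

Plotted time is raw time / N — recruitment attempts per half-nucleosome.
Samples are taken every `sample_interval` (default 1.0) plotted units; a
sample records the state that held when the boundary was crossed.

### Rate multipliers

Per-enzyme multipliers act on acceptance: an otherwise acceptable recruited
move by enzyme *e* is accepted with probability
m<sub>e</sub> / max(1, max<sub>e</sub> m<sub>e</sub>). Lowering a rate below
1 thins that enzyme's moves; raising one above 1 instead thins all others,
keeping the total recruitment attempt rate at 1. Absolute time scales are
therefore defined only up to this convention, which matters when comparing
runs with different multiplier maxima. The `nurd` knob deliberately scales
*both* the direct deacetylation rate and the PRC2:KDM:NURD multiplier —
they are the same enzyme in two recruitment contexts, and suppressing only
one of them cannot produce the blocked acetyl+ubiquitin regime that very low
NURD, PR-DUB and beta are expected to give. Both channels remain
independently settable (`nurd_direct`, multiplier `nurd`).

### Randomness

All randomness flows from `config$seed` through R's RNG in a frozen
consumption order (four channel uniforms, then the move-specific draws, then
any replication mask). The test suite contains an R-level reference stepper
built from the exported per-move operations that reproduces the compiled
engine bit for bit; this is the contract that keeps fixed-seed trajectories
reproducible across versions.

## Analyses

* `category_occupancy()` — per-sample fractions of whole nucleosomes per
  category and their time average. Samples are equally spaced, so the
  time-weighted average is the sample mean; no burn-in is discarded (the
  reference analyses average over the full 50,000-unit run, and the default
  initial condition — all-unmodified — loses memory within tens of time
  units under the default rates).
* `landscape()` — 12 × 12 time-averaged occupancy over the 144 ordered
  whole-nucleosome states. Category-wise sums of landscape cells equal the
  category averages (tested as a two-path consistency check).
* `classify_regime()` — active / silent / bistable / other. A sample is in
  the active (silent) zone when >60% of nucleosomes are category 1
  (category 5). Zone visits are segmented into epochs; by default samples in
  neither zone continue the current epoch (flicker through the middle does
  not split an epoch; a `strict` mode is provided). A run is **bistable**
  when there are at least 2 transitions in each direction and both epoch
  types have mean lifetime ≥ 40 plotted units. "Multiple transitions" is
  operationalised as ≥2 round trips, and "average lifetime of 40 time
  units" as the *mean* epoch lifetime; both are configurable
  (`bistability_params()`). Non-bistable runs are called active (silent)
  when the time-averaged category-1 (5) occupancy exceeds 50%, else other.
* `tail_coexistence()` — fraction of H3K27me3-bearing halves that also carry
  K4/36me (states 9–10 over states 9–12): the tail-level co-occurrence that
  mass-spectrometry measures.
* `pairwise_bivalent_fraction()` / `mark_ratio_in_double_marked()` —
  nucleosome-level co-occurrence of opposing marks, and the K27me3:K4me
  half-count ratio among double-marked nucleosomes (falls from the silent to
  the active regime).

## Sweeps and the reference triptych

`grid_sweep()` runs one- or two-parameter grids (2-fold spacing by default —
every reference perturbation in this system is a 2-fold step) with several
seeds per cell and a majority-vote regime call. Per-cell seeds are hashed
from the base seed, the parameter *values* and the replicate index, so cells
are independent of execution order and can be run concurrently.

`reference_triptych()` locates the three reference settings along the NURD
axis. A subtlety decided during development: the balanced bistable point is
generally *not* a power of two of the default rate. Anchoring a 2-fold
ladder at 1.0 brackets the transition but its gridpoints land on strongly
asymmetric bistable runs (~90/10 dwell-time split), whose landscapes show
only one corner peak. Since the defining property of the reference triplet
is that a two-fold change *in either direction from the bistable point*
switches the system to a stable state, the procedure brackets the transition
on the 2-fold ladder, geometrically bisects to the most balanced bistable
run (minimal |avg cat1 − avg cat5| among bistable calls — the intermediate
situation whose landscape peaks at both extreme corners), and takes the
flanking settings at half and double that value. At the default
parameterisation this yields NURD ≈ 0.08 / 0.16 / 0.32 (active / bistable /
silent).

The tail co-occurrence statistic instead follows its prescribed setup
exactly: raise NURD in 2-fold steps from 1.0 until category 5 dominates the
time average — at the defaults that is NURD = 1.0 itself — and measure over
five seeded runs (≈ 9–10%).

## What the synthetic fixtures do and do not establish

`make_telegraph_fixture()` builds deterministic square-wave trajectories
(constant array per epoch). These validate the regime classifier's decision
boundary — dwell times of 100 units must be called bistable, dwell times of
5 must not — independently of the simulator. They do not emulate the
fluctuating within-epoch composition, partial excursions or asynchronous
nucleosome switching of real simulations, so a green detector test
establishes correctness of the segmentation and thresholds, not power on
marginal trajectories; the simulation-based criteria cover those.

## Numerical choices and degenerate inputs

* A zero-rate channel yields an infinite waiting time but still consumes its
  uniform, so the RNG stream layout is parameter-independent.
* Enzyme actions that cannot apply are no-ops, not errors; a recruitment
  step may legally change nothing (its time still elapses).
* `duration = 0` returns the initial sample only; `tail_coexistence` and
  `mark_ratio_in_double_marked` return `NaN` (flagged, not an error) when
  their denominators are empty.
* Sample boundaries crossed by a step record the pre-move state (the state
  that held during the interval); a boundary sample in the telegraph
  fixture belongs to the ending epoch.
* Configs are JSON rather than TOML: no TOML parser is available among the
  package's dependency set, and the config schema is flat enough that the
  format carries no cost.

## Known limitations

* Absolute rates are uncalibrated (no quantitative enzymology is available);
  all conclusions are about relative parameter changes and regime structure.
* The acceptance-probability convention ties the absolute time scale to the
  multiplier maximum; comparisons across configurations with different
  maxima should use regime-level statistics, not raw event counts.
* With ~10 whole nucleosomes, category fractions are coarse (steps of 0.1),
  which is why dominance thresholds are crossed in discrete jumps.
* The regime classifier sees the sampled series only; dwell times at or
  below the sample interval are invisible.
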