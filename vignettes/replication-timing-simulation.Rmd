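---
title: "Modeling DNA replication timing with replisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling DNA replication timing with replisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replisim)
```

## The model and its assumptions

`replisim` treats replication timing as an emergent property of three
ingredients: a per-bin initiation probability landscape (IPLS), a fixed
pool of replication forks per cell, and unbiased stochastic search. A cell
in S phase repeatedly lets each free pair of forks pick a uniformly random
*unreplicated* bin; the pick fires with the IPLS probability at that bin,
and the fired origin is then extended bidirectionally at constant velocity
(50 bp/s, one bin per sweep) until forks collide with replicated DNA or
reach a chromosome end, at which point they return to the pool and become
available for new initiations. S phase ends when every bin is replicated;
the cell rests in G for a normally distributed number of sweeps and starts
over. Timing is never imposed: early-replicating regions are simply those
dense in high-probability bins, which win the stochastic race more often.

The key assumptions, all deliberate simplifications:

* **Cells and forks are independent.** No licensing, no checkpoint
  signaling, no fork-fork interactions beyond passive collision.
* **Constant fork velocity.** One bin per sweep everywhere; slower or
  pausing regions can be emulated with a per-bin `fork_progress` column,
  but velocity never varies continuously.
* **Memoryless initiation.** The probability a bin fires is the same at
  every attempt; there is no refractory period and no dependence on time
  in S beyond the shrinking pool of unreplicated bins.
* **One chromosome at a time.** The fork pool is per chromosome; a genome
  is simulated by running chromosomes separately (the fork count scales
  as roughly one fork per 80 Mb of genome).

## Parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `binsize` | bp | 500 | spatial resolution; also sets the time step, `sweep_seconds(binsize) = binsize / 50` s |
| `ncells` | cells | 1000 | independent cells in the ensemble |
| `nfork` | forks/cell | 50 | fork pool; initiation consumes pairs |
| `ntherm` | sweeps | 80000 | burn-in that desynchronizes the initially all-G population; cycles beginning before this horizon are discarded |
| `nmeas` | epochs | 2000 | measurement snapshots |
| `stepsize` | sweeps | 20000 | spacing between snapshots |
| `pprogress` | probability | 1 | per-sweep fork advance probability (per-bin override: IPLS column 3) |
| `prelease` | probability | 0 | per-sweep stochastic fork release (per-bin override: IPLS column 4) |
| `g_mean`, `g_sd` | sweeps | auto | G-phase duration distribution, truncated at 1 sweep |
| `seed` | — | 1 | master seed; each cell derives an independent stream |

The defaults are the tool's standard operating point at 500 bp resolution.
For the small test-bench problems in this package the thermalization and
measurement schedule are scaled down to the relaxation time of the problem
at hand (a few multiples of one cell cycle), which is the only thing
burn-in needs to cover.

**G-phase duration.** Only the existence of a normal G duration matters to
the model (it desynchronizes the population); its parameters are not
dictated by the biology being tested. When unspecified, `g_mean` is set to
the landscape's expected S duration, estimated from a 16-cell pilot run,
and `g_sd` to 10% of that — a cycle that spends comparable time in G and S
with mild variability, which mixes the ensemble quickly.

**Initiation attempts per sweep** (`init_rule`). Two readings of the
firing step are defensible: one attempt per free fork *pair* per sweep
(opportunity scales with free replication factors) or one attempt per
*cell* per sweep. `replisim` implements both; `per_pair` is the default
because it makes the free-factor pool meaningful, and the independent
reference simulator implements both rules so each position of the switch
is cross-validated.

## Within-sweep event order and tie-breaks

The order is fixed: advance → stochastic release → initiation →
completion check. Consequences worth knowing:

* A cell entering S at the start of a sweep may already initiate in that
  sweep.
* An initiation marks its own bin replicated at the firing sweep; the two
  forks extend from it on subsequent sweeps.
* When two forks converge on the same unreplicated bin in one sweep, the
  fork with the lower pool index takes it and the other is released — a
  deterministic tie-break, so runs are exactly reproducible.
* A blocked advance releases only the blocked fork.
* Release draws happen only where `fork_release > 0`; with the default 0
  the fork pool is recycled purely by collisions and boundaries.

## Randomness and determinism

Each cell owns a xoshiro128++ stream seeded from the master seed and the
cell index. Results are therefore bit-identical across runs with the same
configuration and independent of iteration order — which is also why the
`threads` flag cannot change results (it is accepted for interface
compatibility; execution is serial).

## Landscapes

`bedgraph_to_ipls()` converts genomic signal (typically DNase
hypersensitivity) into probabilities: coverage-weighted mean per bin,
uncovered base pairs contributing zero, then max-normalization so the
strongest bin gets probability 1. Max-normalization is a design choice,
not a fact of the data: only *relative* amplitudes shape the timing
program, and the graded (rather than thresholded-binary) reading of the
signal preserves the most information. Sum-normalization is available
(`normalize = "sum"`) for workflows that want probabilities on a
per-genome budget; thresholding, if desired, can be applied to the track
before conversion. Bins with zero signal remain in the landscape — they
are replicated passively by forks, never by initiation.

## The measurement devices

* `timing_profile()`: per-bin mean replication sweep over completed S
  phases; the normalized column (z-scored, sign-flipped so early = high)
  matches the convention of early/late-ratio timing data. Wavelet
  smoothing of empirical profiles is out of scope — comparisons should
  smooth the empirical side first.
* `flow_sort()`: gates S-phase snapshot cells by replicated fraction
  (half-open intervals, last closed, G cells never sorted) and counts
  replicated bins per gate; also returns an S50-style weighted-midpoint
  timing.
* `single_molecule_stats()`: eyes, holes, and eye-to-eye distances per
  snapshot cell, pooled into equal-width time-in-S bins. Eye-to-eye is
  center-to-center of adjacent eyes; eyes truncated by a chromosome end
  count as eyes but are excluded from eye-to-eye, since their centers are
  artifacts of truncation.
* `initiation_rate()`: events divided by exposure (unreplicated-bin
  sweeps), binned by the replicated fraction at the event's sweep.
  Exposure is accumulated during simulation on a fixed 1000-bin fraction
  grid and re-binned at query time; bins with zero exposure report `NA`.
* `nascent_profile()`: initiation events per bin — the simulated analog
  of short-nascent-strand enrichment.
* `indices()`: S-phase fraction and fork-pool engagement per snapshot.

## What the synthetic generator does and does not emulate

`synthetic_landscape()` produces delta, multi-delta, uniform, and
Gaussian-peaks landscapes. Delta landscapes make the dynamics exactly
solvable (the timing profile is the minimum bin distance to an origin),
which anchors the test suite with zero-tolerance checks; uniform
landscapes emulate random-initiation systems such as early *Xenopus*
embryos; peaks landscapes are a cartoon of clustered open-chromatin
origins. None of them reproduce real chromatin: no signal noise, no
mappability gaps, no correlation structure between neighboring origins.
Tests passing on these landscapes validate the *mechanics* (fork
accounting, timing arithmetic, instrument geometry) — they do not certify
prediction accuracy on real DNase data, which depends on data quality and
resolution choices outside the simulator.

A related subtlety the test suite documents: on a uniform landscape the
*sampler* is uniform, but observed initiation events still concentrate
near chromosome ends, because interior bins are more often replicated
passively by forks arriving from both sides and so spend less time
eligible. The uniformity test therefore freezes fork movement
(`fork_progress = 0`, `fork_release = 1`) to isolate the sampler.

## Numerical choices and degenerate inputs

* Replication sweeps are integers; means over cycles are accumulated in
  double precision with per-bin sums and sums of squares (`timing_se()`
  exposes the Monte Carlo error).
* An all-zero landscape is rejected at construction: S phase could never
  complete.
* G durations are rounded to integer sweeps and truncated at 1.
* The pilot estimator of `g_mean` aborts if a pilot S phase exceeds 1e8
  sweeps, catching near-degenerate landscapes early.
* IPLS files are written with 17 significant digits so the read/write
  round trip is exact.
* `reference_simulate()` (the independent plain-R oracle) refuses more
  than 12 bins or 4 forks: it exists to be obviously correct, not fast.

## Test-bench problem sizes

The acceptance suite exercises: exact closed-form timing up to 10,000
bins; engine-vs-oracle agreement on 3–6-bin landscapes with at least
10,000 completed cycles per side (3 standard errors); combing trends on a
300-bin, 5-peak landscape with 40 cells; and velocity recovery from a
single cell. These sizes are chosen to make every stochastic comparison
well-powered while keeping each oracle case under a minute of runtime.

## Known limitations

* No replication licensing or origin refractoriness; re-replication is
  prevented only by the replicated-bin mask.
* No inter-chromosomal fork sharing; `nfork` must be sized per
  chromosome.
* The flow-sorter output is an idealized gate count — no sequencing-read
  simulation, fragment-length effects, or mappability.
* Multi-origin deterministic landscapes reproduce the minimum-distance
  closed form only in cycles where all origins fire on the same sweep;
  asynchronous firing adds a stochastic offset per origin, which is the
  realistic behavior but not a closed form.
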