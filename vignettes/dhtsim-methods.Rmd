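---
title: "Models and methods behind dhtsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dhtsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhtsim)
```

This vignette is the package's own account of its models: what each stage
assumes, which parameters matter, where the design was genuinely open, and
what the synthetic-data tests do and do not show about real experiments.

## The tile model and the activation cascade

A DNA hairpin tile (DHT) is a double-crossover (DX) motif assembled from
four strands: a core strand bridging the two crossover junctions, strands
carrying 5' single-stranded sticky ends, and a hairpin strand whose stem
keeps the tile metastable. The sticky end adjacent to the hairpin serves as
a toehold for strand displacement. We represent strands as plain 5'→3'
sequences with 0-based, half-open domain annotations (`core`, `sticky_end`,
`stem`, `loop`, `toehold`); complementarity is always checked as the
reverse complement of the partner's annotated interval.

`validate_tile()` enforces the design rules as *data* (violation records),
not exceptions: four strands per tile, in-bounds non-overlapping domains,
stem halves that are exact reverse complements, toeholds not covered by any
stem duplex, and declared inter-tile sticky pairs that pair exactly.

`sdr_cascade()` replays activation topologically: a hairpin is closed until
the tile's toehold is invaded, and opening is a flag, not a free-energy
computation — the monomers are kinetically trapped by the closed loop's
topological constraint, so no nearest-neighbor thermodynamics is needed to
express the mechanism. The invader's business end is its 3'-terminal
segment; a loop *contains* its active segment at the 3' end, which lets
loop lengths exceed the 6-nt segment without changing the logic. The
cascade closes when a newly exposed segment is sequence-identical to the
initiator's active 3' segment (event 3 re-invades the first tile). Four
6-nt segments have fixed roles: `TGTCAC` (A's toehold), `TGAACC` (A's loop,
which invades B's toehold `GGTTCA`), and `GTGACA` (B's loop segment,
identical to the initiator's 3' end). Note the arithmetic that makes the
cycle work: `GTGACA` is the reverse complement of `TGTCAC`, and `TGAACC`
of `GGTTCA`.

Crossover geometry uses the canonical B-DNA constants (0.34 nm/bp rise,
2.25 nm diameter, 10.5 bp/turn). The separation between intermolecular
crossovers, in nucleotides, is converted to helical turns and rounded to
the nearest half-turn: a half-integer count (26 nt → ≈2.5 turns) places the
next monomer on the same side, giving linear 1D filaments; an integer count
(32 nt → ≈3 turns) places it on the opposite side, the 2D-growth geometry.
We encode this parity rule exactly as stated rather than re-deriving a
helical phase convention — the mapping between half-turn parity and side
depends on the reference frame of the first junction, which the design
fixes implicitly. Tile dimensions come from the same constants; the ~5 nm
width is two helix diameters plus a configurable 0.5 nm inter-helix gap.

## The living chain-growth simulator

Concentrations enter only through the monomer-to-initiator ratio
`[M]0/[I]0`; the initiator ensemble is `n_initiators` discrete chains
(default 10,000) and the monomer pools are integer counts, so volume is
implicit. Growth is irreversible (no depolymerization at room temperature)
and strictly alternating: every chain is `I-[A-B]_k` or `I-[A-B]_k-A`.

**Ideal mode** is the classical fast-initiation living limit: every
initiator nucleates a chain, and A-B pairs are the propagation unit — each
pair event lands on a uniformly random chain until the pools are exhausted.
The per-chain pair count is then Multinomial(pairs, chains), i.e. Poisson
with mean μ = `ratio_MI` in the many-chain limit, which is the textbook
living-polymerization chain-length distribution and the model the measured
Poisson-shaped label histograms presuppose.

The paired unit is a deliberate modeling decision with real physics behind
it. We prototyped the alternative — single-monomer events with the species
forced by each chain's terminus — and its exhaustion endpoint is *not*
Poisson: with equal pools, the A pool always runs out first (A-consumption
leads B by the number of odd-length chains), the B leftover then exactly
completes every odd chain, and the final pair counts are underdispersed by
about a factor of two. That completion effect is visible in **kinetic
mode**, which keeps full two-species stochastic events
(`I + A → I-A*` at `k_init`; `chain* + monomer` at `k_prop`, defaults
`k_init/k_prop = 100`): its mean matches ideal mode exactly, its variance
is systematically narrower. Since the system's rate constants are unknown,
kinetic mode is a sensitivity tool, not a fit.

Two closed forms anchor the tests. For detectable chains (at least one
tile), the tile-unit dispersity is

$$\mathrm{PDI}_{\ge 1} \;=\; \frac{(1+\mu)\,(1-e^{-\mu})}{\mu},$$

because Lw is unaffected by censoring zero-length chains while Ln carries
the zero-truncation factor; this converges to the familiar $(1+\mu)/\mu$
by μ ≈ 5 and makes the PDI-versus-ratio curve slightly non-monotone below
μ ≈ 2. And with full labeling of A monomers, the fraction of detectable
ratio-1 chains carrying exactly one label is the zero-truncated Poisson(1)
value $e^{-1}/(1-e^{-1}) = 58.2\%$.

**Thermal mode** is the initiator-free step-growth control: at extent of
reaction p, each junction along the monomer sequence is bonded
independently with probability p, giving the Flory most-probable
distribution (mean 1/(1−p), PDI → 1+p; p = 0.99 gives PDI ≈ 1.99). The
study's thermal control may not have reached full conversion, so p is a
free parameter.

**Re-feeding** (`extend_population()`) adds monomers to the pools and
resumes pair allocation on the *existing* chains only — the living
restart. Mean length is therefore linear in the cumulative ratio, and the
chain count never changes. The initiator strand contributes 0 nm of
contour by default (a ~14-nt single strand is below AFM contour
resolution); this is exposed as `initiator_nm`.

## Dispersity statistics and Poisson fits

`dispersity_summary()` implements the four estimators on lengths $L_i$
with multiplicities $N_i$: $L_n=\sum N_iL_i/\sum N_i$,
$L_w=\sum N_iL_i^2/\sum N_iL_i$, the **population** standard deviation
(divisor N, not N−1 — matching the estimator the quantities are defined
with), and PDI $=L_w/L_n$. Statistics are always computed on raw values;
histogram binning is a display concern. Zero or negative lengths are
domain errors: an undetectable object is dropped (and counted) upstream,
never averaged.

`fit_poisson()` fits label histograms by maximum likelihood. Untruncated,
the MLE is the weighted mean. Zero-truncated — the default for
streptavidin and photobleaching counts, since a chain with zero labels is
invisible on the surface — the MLE solves
$\lambda/(1-e^{-\lambda}) = \bar k$ by a bracketed `uniroot` with tolerance
1e-8 (the ZTP mean exceeds λ, so doubling the bracket upper end always
finds a sign change). A truncated sample with all mass at k = 1 pushes λ
to the zero boundary; that is reported as `boundary = TRUE`, never
silently. Whether the original histogram fits were zero-truncated, and
whether λ was fixed or fitted, is not stated in the source material; both
modes are available and neither is asserted as "the" analysis.

## Photobleaching synthesis and step counting

`synthesize_trace()` builds a staircase starting at
`n_steps × step_height`, dropping one unit at exponential dwell times
(memoryless single-fluorophore photophysics), sampled at a uniform frame
grid (default 3.88 Hz, the EMCCD acquisition rate) with i.i.d. Gaussian
noise. Camera gain statistics, blinking kinetics and drift are out of
scope; ground truth is carried in `meta`.

Step counting was done manually in the original study; the package defines
an explicit, tunable algorithm instead. `count_steps()`:

1. fits a piecewise-constant signal by greedy binary segmentation,
   accepting a split while the squared-error gain exceeds a penalty
   (default `1.5 σ² log n`, with σ estimated as `mad(diff(x))/√2`; the
   rate is BIC-style, and the constant is set slightly below the classical
   2 because step 3 cleans up sub-unit false positives);
2. merges upward jumps (blinking) and drops below `min_step`
   (default 3σ), so plateau means are monotone non-increasing;
3. quantizes each drop against a unit step height, reporting `n_events`
   (the fluorophore count) alongside `n_steps` (the number of change
   points).

Step 3 exists because two fluorophores bleaching within one frame interval
produce a single double-height drop: at the default 3.88 Hz and 2 s mean
dwell this happens to ~12% of adjacent pairs, so `n_steps` alone
systematically undercounts at high copy number no matter how good the
detector is. Quantization is also what makes aggressive merging safe — a
merged change point's intensity loss is preserved in the neighboring drop.
The unit height is best calibrated across an imaging batch
(`count_steps_batch()`, median of all fitted drops; used by
`step_histogram()`); per-trace, the median drop is the fallback. On
seeded synthetic batches (200 traces per condition, 60 s, 2 s dwells) the
batch-calibrated counter recovers the true fluorophore number in ≥95% of
traces for SNR ≥ 5 and up to 10 fluorophores. The per-condition
percentages observed in the real experiment reflect labeling and detection
efficiencies that a desk simulation cannot reproduce; what the package
asserts is the recovery surface of its own algorithm plus the qualitative
mode of the count histogram.

## The elastic-rod fluctuation model

Filament mechanics uses a deliberately one-dimensional rod, not a full 3D
finite-element model: nodes at per-bp arc positions, per-element bending
stiffness, and two independent transverse bending directions of an
Euler–Bernoulli discretization. The beam parameters are the standard
B-DNA values — bending stiffness 230 pN·nm² (persistence length
230/4.114 ≈ 55.9 nm at 298 K), stretching modulus 1100 pN and torsional
stiffness 460 pN·nm², both stored but excluded from the RMSF since the
soft modes of slender rods are bending; nicks soften bending 100-fold;
single-stranded segments (sticky ends, loops) are very soft bending
elements with stiffness `kBT × 1 nm` rather than a calibrated
freely-jointed chain, whose parameters are not available. The DX
cross-section is approximated as twice the single-helix stiffness
(`dx_multiplier = 2`), ignoring the parallel-axis offset term; designs are
`dsDNA(bp)`, `monomer` (soft ends + DX core) and `filament(n_AB)` (DX
cores joined by nicked 1-bp elements). Rods are coarse-grained in duplex
runs only, capped at 2000 nodes; the largest stock design (`n_AB = 10`,
≈970 nodes) stays below the cap at full resolution.

`compute_rmsf()` assembles the hinge stiffness matrix (hinge stiffness =
harmonic mean of the adjacent elements over the hinge's arc length —
springs in series, so a nick dominates its junction), projects out the
exact rigid-body null space {translation, rotation} by QR, inverts the
reduced matrix by Cholesky (a failure there is reported as a singular
non-rigid null space), and gives each mode kBT by equipartition; the
per-node RMSF sums the two transverse directions. The computation is
deterministic. Its independent check is a Monte-Carlo oracle that samples
hinge angles i.i.d. from their Boltzmann variances, rebuilds node
positions, and removes the best-fit line — a different route through the
same quadratic model, agreeing within 5% on ≤50-node rods.

Relative compliance is defined against a 24-bp duplex (8.16 nm):
`kb = B_eff / L^exponent` with `B_eff` the length-weighted harmonic mean
of element stiffness. The verbal definition in the source ("decreases
inversely proportional to its length") implies exponent 1, while
cantilever beam theory gives exponent 3; we default to 3 and expose 1,
since only ratios and orderings are asserted either way. Numeric RMSF
values for the published designs are not available in the accessible text,
so the package asserts orderings (24-bp duplex ≤ monomer ≤ I-A-B ≤
I-[A-B]₅ ≤ I-[A-B]₁₀ in max RMSF, compliance ratios > 1), not magnitudes.

## Synthetic data: what it does and does not emulate

`generate_tile_set()` builds sequence sets by constrained random filler:
the four cascade segments occupy their fixed roles, stems are
self-complementary by construction, declared sticky pairs pair exactly,
filler is rejected if it creates stray copies of any reserved segment
(including across piece junctions and in reverse-complemented sticky
ends), and among surviving candidates the lowest 6-mer symmetry score is
kept — a greedy nod to sequence-symmetry minimization, not a full design
algorithm. Stems shorter than 6 nt are refused as infeasible. The real
strand sequences live in supplementary material that is not reproduced
here; generated sets preserve every printed sequence fact while being
openly synthetic.

`gen_afm_lengths()` adds Gaussian measurement noise (default 8 nm), an
optional tip-broadening constant, and a detection floor (default 10 nm)
below which objects are dropped and counted. These defaults are
instrument-plausible package values, not measured ones — the study's AFM
error is unreported — so tests treat them as a sensitivity knob. Measured
PDIs include this noise, which is why a noisy sample's PDI exceeds the
noiseless tile-count PDI. `gen_trace_batch()` gives each chain a trace
with one fluorophore per A monomer. What passing tests show is internal
consistency of simulator, statistics and detectors under a controlled
noise model; they do not show that real AFM or TIRFM data match these
noise models.

## Problem sizes and reproducibility

Simulations in tests and in `scripts/acceptance.R` use 10,000 initiators
(10⁶ monomer units for the thermal control), 200 traces per photobleaching
condition, and ≤1,000-node rods — sizes at which every sampling error
relevant to a 2–5% assertion is comfortably small and the whole suite runs
in well under a minute of compute. Every stochastic function takes a
`seed` and restores the caller's RNG state; `run_pipeline()` derives
per-stage sub-seeds from one master seed, so identical configurations
produce byte-identical outputs (checksummed in its manifest).

## Known limitations

* No thermodynamics: hairpin opening is topological, and melting,
  leakage, and off-pathway assembly are out of scope (the no-initiator
  control is represented by an empty cascade, not a leak rate).
* The ideal/kinetic dichotomy brackets, but does not fit, the real
  kinetics; rate constants are arbitrary units.
* The rod model is 1D: no torsion-bend coupling, no sequence-dependent
  stiffness, no electrostatics, and the DX cross-section multiplier is a
  convention.
* 2D growth is covered only by the crossover-parity predicate; platelet
  lattice assembly is not simulated.
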