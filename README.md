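# dhtsim

Simulation and single-molecule analysis of **chain-growth copolymerization
of DNA hairpin tiles (DHTs)** into one-dimensional nanofilaments.

DHTs are double-crossover (DX) DNA tiles carrying a closed hairpin that
makes them metastable: mixed A and B monomers do not polymerize on their
own. A single-stranded initiator **I** opens tile A's hairpin through a
toehold-mediated strand displacement reaction (SDR); the exposed loop of A
invades B's toehold, and the segment exposed on B is identical to the
initiator's active 3' end, so the cascade regenerates itself and the chain
grows as strictly alternating `I-[A-B]_n`. Growth happens only at
persistent active termini — a *living* polymerization — so chain lengths
follow Poisson statistics, the polydispersity index (PDI) stays near 1, and
growth resumes when fresh monomers are fed.

The package implements, in base-R S3 style:

* **Tile model** — strand/domain representation of tiles
  (`strand_spec()`, `tile_spec()`, `reaction_system()`), design-rule
  validation (`validate_tile()`: sticky-pair and stem complementarity,
  single-stranded toeholds), the activation cascade replay
  (`sdr_cascade()`), and crossover geometry (`crossover_turns_and_side()`:
  26 nt ≈ 2.5 helical turns → same-side 1D growth; 32 nt ≈ 3 turns →
  opposite-side 2D growth).
* **Chain-growth simulator** — `simulate_living()` (fast-initiation ideal
  mode and a full two-species Gillespie kinetic mode),
  `simulate_thermal()` (initiator-free step-growth control, Flory
  distribution, PDI → 1 + p), `extend_population()` (living restart by
  stepwise re-feeding).
* **Dispersity statistics** — `dispersity_summary()` computes
  Ln = ΣNᵢLᵢ/ΣNᵢ, Lw = ΣNᵢLᵢ²/ΣNᵢLᵢ, the population σ, and PDI = Lw/Ln;
  `fit_poisson()` fits label-count histograms by maximum likelihood,
  including the zero-truncated Poisson for surface-invisible zero-label
  chains.
* **Photobleaching** — `synthesize_trace()` builds staircase
  intensity–time traces (exponential dwells, Gaussian noise, 3.88 Hz
  default frame rate); `count_steps()` / `count_steps_batch()` count
  bleaching steps by penalized least-squares change-point detection with
  blinking rejection and unit-height quantization.
* **Mechanics** — `build_rod()` discretizes dsDNA, a DHT monomer, or a
  filament as an elastic rod (bending stiffness 230 pN·nm², 100-fold
  softening at nicks, soft single-stranded ends); `compute_rmsf()` gives
  per-node thermal fluctuations at 298 K by normal-mode analysis;
  `relative_compliance()` reports k_b(dsDNA-24bp)/k_b(filament).
* **Synthetic data + pipeline** — `generate_tile_set()` builds
  sequence sets honoring the fixed cascade segments
  (`TGTCAC`/`TGAACC`/`GGTTCA`/`GTGACA`), `gen_afm_lengths()` and
  `gen_trace_batch()` emulate measurements, and `run_pipeline()` ties the
  stages together with one seed and a checksummed manifest. A thin CLI
  lives at `inst/scripts/dht.R`.

## Worked example

```r
library(dhtsim)

# a valid tile system whose cascade closes
sys <- generate_tile_set(seed = 1)
sdr_cascade(sys)[, c("invader", "segment", "target", "closes")]
#>   invader segment target closes
#> 1       I  GTGACA      A  FALSE
#> 2       A  TGAACC      B  FALSE
#> 3       B  GTGACA      A   TRUE

# living copolymerization at [M]0/[I]0 = 10
pop <- simulate_living(ratio_MI = 10, n_initiators = 10000, seed = 42)
summary(pop)
#> Population (ideal mode): 10000 chains (10000 with >= 1 tile)
#>   mean tiles/chain: 20.000 (mean contour 320.0 nm)
#>   tile-unit Ln = 20.000, Lw = 21.997, PDI = 1.0999
#>   free_A = 0, free_B = 0, unreacted initiators = 0
```

20 tiles × 16 nm ≈ 320 nm mean contour length, and PDI ≈ 1.1 — the
(1 + μ)/μ Poisson signature of living growth (μ = 10 A-B pairs). A thermal
control at 99% conversion (`simulate_thermal(0.99)`) gives PDI ≈ 1.99 at
the same software settings, the step-growth contrast.

```r
# count photobleaching steps in a synthetic trace batch (SNR = 5)
traces <- lapply(1:100, function(i)
  synthesize_trace(n_steps = 2, step_height = 1, noise_sd = 0.2, seed = i))
table(vapply(count_steps_batch(traces)$calls, `[[`, 0L, "n_events"))
#>  1  2  3
#>  2 96  2
```

96% exact recovery at signal-to-noise 5; the misses are traces whose two
bleaching events fall in the same 258 ms frame and whose merged drop the
unit-height quantization could not resolve, or near-threshold noise calls.

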