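# mitoaxon

Quantification of mitochondrial fission, fusion, transport, and
actin-patch/Drp1 colocalization along embryonic sensory axons imaged by
timelapse fluorescence microscopy.

## The problem

Neurotrophin signaling triggers a burst of mitochondrial fission along
sensory axons, after which a new steady state of mitochondrial length and
density is maintained. Quantifying that biology from timelapse stacks
requires a chain of measurements, each with sharp operational rules:

- **Event calling.** A *completed fission* is called only when the
  fluorescence in the gap between the two emergent mitochondria has
  decreased to the background level and their edge-to-edge separation
  exceeds 0.6 µm (5 pixels at 0.12 µm/pixel); transient constrictions that
  re-widen are not fission. A *fusion* requires a uniform-intensity product
  whose length is additive of the two partners, with redistribution of
  signal when they differed in brightness.
- **Transport.** Tracks are classified (stalled / oscillating /
  transported at the 1 µm excursion bound), decomposed into runs terminated
  by pauses ≥ 6 s, with per-bout velocities, summed run lengths and
  direction switches.
- **Morphometry.** Length and number of mitochondria in the distal 50 µm
  of the axon shaft (growth cone excluded), density per 10 µm, branch
  counts (projections > 10 µm), and the mass index
  `mean length × density / 10 µm`.
- **Colocalization statistic.** For each of n fission events, let A be the
  mitochondrion's length and B the summed length of actin patches present
  on it at the first frame where fission is evident. The probability that a
  *randomly placed* fission site would overlap a patch is C = B/A, and the
  probability of observing patch overlap at all n sites by chance is
  ∏ᵢ Cᵢ, accumulated in log space.
- **Fluorescence.** Total integrated immunofluorescence
  (area × background-subtracted mean) and FRAP recovery
  `100·(Iₜ − I₀)/(I_pre − I₀)` with the 90%-bleach inclusion rule.
- **Statistics.** Normality-routed test selection (Lilliefors KS →
  Welch t / Mann–Whitney; ANOVA + Bonferroni / Kruskal–Wallis + Dunn's;
  Fisher exact for counts).

Because the raw recordings are large and the rules are easy to get subtly
wrong, the package ships an event-driven **simulator** of axonal
mitochondria (fission, fusion, run-and-pause transport, actin patches,
Drp1 puncta) with a microscope-like renderer (PSF blur, additive overlap,
Poisson–Gaussian noise) and exact ground-truth logs, so every stage of the
pipeline is validated offline against known truth.

## Worked example

```r
library(mitoaxon)

# simulate one axon at the imaging conditions (110 frames, 3 s, 0.12 um/px)
cfg   <- sim_config(seed = 42, fission_prob_per_10min = 0.3)
truth <- simulate_dynamics(cfg)
stacks <- render_stack(truth, cfg)

# run the pipeline: profiles -> segments -> tracks -> events -> patches
res <- analyze_axon(stacks, pixel_size = cfg$pixel_size,
                    frame_interval = cfg$frame_interval)
res$summary
#>   n_mito_frame0 density_per_10um mean_length_um mito_mass n_fission n_fusion
#> 1             8         1.333333       2.348587  3.131449         2        0

# the random-overlap probability on the bundled 20-event reference dataset
tab <- reference_overlap_table()
summary(tab)
#>         quantity      mean       sem  n
#> 1  mito_length_A 8.3180000 0.8154620 20
#> 2 patch_length_B 0.8310000 0.1553788 20
#> 3   proportion_C 0.1035384 0.0097288 20
random_overlap_probability(tab)
#> $p_full   2.337069e-21      # full-precision product of C = B/A
#> $p_table  1.752828e-21      # product of the two-decimal table proportions
```

The mean length of fissioning mitochondria is 8.3 µm (SEM 0.8), the mean
summed patch length 0.83 µm (SEM 0.16), and the chance probability of
patch overlap at all 20 observed fission sites is ≈ 1.75 × 10⁻²¹ in the
two-decimal dialect of the source table — overwhelming evidence that actin
patches mark fission sites rather than coinciding with them.

The numbered scripts under `analysis/` run the full study: fixture
generation, zero-noise oracle validation of event calling (precision =
recall = 1 over 50 axons), kinetic parameter recovery (fission probability
0.30/10 min, post-fission transport 0.80, run-switch probability 0.55),
the overlap statistic with its null calibration, and a group comparison on
noisy renders. Each writes its tables under `results/`.

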