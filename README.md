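# dyadsync

Interpersonal neural synchrony from dyadic fNIRS hyperscanning, end to
end: raw two-wavelength intensities and conversation-coding logs in,
epoch-resolved wavelet-coherence synchrony, surrogate null distributions
and beta mixed-model inference out.

The package is aimed at developmental and social neuroscientists who
record two interacting people (here: mothers and preschool children in
free conversation) with a 16-channel, two-wavelength fNIRS montage over
bilateral dlPFC and TPJ, and who want a tested, scriptable, deterministic
version of the standard analysis chain:

1. **Preprocessing** — optical density, db5-MODWT wavelet despiking,
   automated heart-band channel QC (Welch power ratio), zero-phase
   second-order Butterworth band-pass (0.01–0.5 Hz), modified
   Beer–Lambert law (DPF 6 / 5.5, Prahl extinction table).
2. **Synchrony** — Morlet (ω₀ = 6) wavelet transform coherence per
   homologous channel pair,

   R²(s,t) = |S(W_xy/s)|² / ( S(|W_x|²/s) · S(|W_y|²/s) ),

   cone-of-influence exclusion, mean over the 0.06–0.15 Hz band in eight
   consecutive 30-s epochs → a 16 × 8 coherence table per dyad.
3. **Chance levels** — random-pair surrogates (each child × non-partner
   mothers) and amplitude-preserving phase randomization.
4. **Behavior** — turn segmentation from coded utterance events and
   equally-weighted composites for turn-taking, relevance, contingency
   and intrusiveness (plus ICC(2,1) and weighted kappa for reliability).
5. **Inference** — logit-link beta mixed models (glmmTMB, ML/Laplace)
   with dyad random intercepts and uncorrelated random slopes, a
   sequential likelihood-ratio model ladder (null → turn-taking → time →
   turn-taking × time → …), link-scale trend contrasts for early vs late
   epochs, and the original-vs-random-pair comparison.
6. **Synthetic dyads** — a seeded generator with known epoch-wise
   coupling κ and a behavior link, emitting raw intensities through the
   forward Beer–Lambert model so every stage has ground truth.

## Worked example

```r
library(dyadsync)

cfg <- pipeline_config(overrides = list(
  simulate  = list(n_dyads = 8L, seed = 1L),
  surrogate = list(n_draws = 5L, seed = 1L),
  model     = list(ladder_through = 3L),
  out_dir   = "demo_out"
))
res <- run_pipeline(cfg)
#> simulated 8 dyads (240 s at 7.81 Hz)
#> preprocessed 8 dyads; 100.0% of channels retained
#> coherence: 8 dyads x 16 channels x 8 epochs (mean 0.419)
#> surrogates (random_pair, 5 draws): original 0.419 vs null 0.403
#> ladder fit through model 3 on 1024 rows

res$pairing$lrts
#>   comparison     chi2 df          p
#> 1   p1 vs p0 7.941949  2 0.01885505
#> 2   p2 vs p1 5.043722  2 0.08031001
#> 3   p3 vs p2 1.231047  2 0.54035788
```

Reading the output: the eight simulated dyads carry true in-band
coupling, so their mean epoch coherence (0.419) sits above the
random-pair chance level (0.403), and adding the pairing indicator to
the null model improves fit (χ²(2) = 7.94, p = .019) — original dyads
are more synchronous than chance. At this small demo size neither the
time effect (p = .080) nor the pairing × time interaction (p = .540)
reaches significance. `demo_out/` contains the coherence, QC, surrogate,
score,
ladder, coefficient and trend tables as TSV plus a JSON manifest whose
config hash and seeds make the run byte-reproducible.

A thin CLI wraps the same functions:

```sh
exec/dyadsync simulate --seed 7 --out sim_out
exec/dyadsync run-all --config demo.yaml
```

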