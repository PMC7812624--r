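# dyadsync pipeline configuration -- fully commented default.
# Every analysis parameter of the mother-child conversation pipeline in
# one place; `run_pipeline(pipeline_config("demo_config.yaml"))` or
# `exec/dyadsync run-all --config demo_config.yaml` runs the whole chain.

chromophore: HbO          # headline analysis; set HbR for the replication

preprocess:
  iqr_alpha: 1.5          # wavelet despiking threshold, IQR units
  cardiac_band_hz: [0.6, 1.5]   # "clear heart band" screen
  power_ratio_min: 0.2    # per-wavelength retention threshold
  low_hz: 0.01            # Butterworth band-pass corners (2nd order,
  high_hz: 0.5            # 12 dB/octave, zero-phase)
  qc: true

wtc:
  band_hz: [0.06, 0.15]   # analysis band (~6-16 s periods)
  epoch_len_s: 30         # 8 epochs over a 4-min conversation
  omega0: 6               # Morlet nondimensional frequency
  dj: 0.0833333333        # 1/12 octave scale resolution

surrogate:
  kind: random_pair       # or phase_randomized
  n_draws: 1000           # random mothers per child
  seed: 1

model:
  ladder_through: 7       # null + Models 1-7
  roi: null               # e.g. [TPJ-L, TPJ-R] for a per-ROI model

simulate:                 # demo input: synthetic cohort with ground truth
  enabled: true
  n_dyads: 4
  seed: 1
  duration_s: 240         # 4-min free conversation
  fs: 7.81                # sampling rate, Hz
  coupling_base: 0.45     # baseline shared-signal weight kappa
  coupling_slope: 0.01    # kappa change per epoch
  behavior_link: 0.02     # slope shift per SD of dyad turn-taking

out_dir: dyadsync_out
seed: 1
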