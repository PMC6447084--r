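# Example declarative analysis for `run_analysis()` / `inst/cli/mrpipe.R run`.
# Synthetic mode: exposure and outcomes are generated at the configured scale.
outcomes:
  CAD:
    theta_true: -0.3
    binary: true
    n_outcome: 184305
    case_fraction: 0.33
  glucose:
    theta_true: 0.15
    n_outcome: 100000
sim:
  n_variants: 58
  r2_target: 0.022
  n_exposure: 150000
prop_pleiotropic: 0.2069   # 12 of 58 variants planted with trait associations
n_boot: 500
mvmr:
  thetas:
    birthweight: -0.2
    bmi: 0.1
power:
  n_outcome: [100000, 184305]
  r2: 0.022
  effect: 0.15
n_traits_bonferroni: 12
seed: 1
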