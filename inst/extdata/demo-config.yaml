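# Demo pipeline configuration: a 151-patient synthetic cohort plus one
# simulated direction of 15 head impulses.
seed: 20260910
n_patients: 151
n_trials: 15
acceleration_thresholds:
  HC: 2500.0
  AC: 1500.0
  PC: 1500.0
blink_cutoff: 350.0
saccade_threshold: 60.0
ms_v_max: 500.0
ms_c: 5.0
ms_tolerance: 0.25
rcft_threshold: -2.0
alpha_remove: 0.1
model: plain_mle
min_trials: 10
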