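# Example study configuration consumed by pipeline_config_from_yaml().
mode: simulate
seed: 42
alpha: 0.05
n_perm: 5000
use_curves: true
heatmaps: false
design:
  n_control: 10
  n_mirror: 12
  n_winner: 12
  n_loser: 11
  interaction_minutes: 30
effects:
  sigma_subject: 0.3
  sigma_dyad: 0.2
  sigma_resid: 0.5
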