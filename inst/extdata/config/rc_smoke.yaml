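# Desk-scale smoke configuration of the RC-circuit workflow.
# The research-scale profile uses n_simulations: 100000 with the same
# prior, summary and noise settings.
simulator: rc_circuit
prior: rc_circuit
summary:
  scheme: pca
  k: 10
noise_variance: 0.01
n_simulations: 2000
seed: 42
out_dir: rc_smoke_out
training:
  max_epochs: 20
  patience: 5
diagnostics:
  resolution: 3
  n_post_samples: 200
  n_ppc_sims: 10
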