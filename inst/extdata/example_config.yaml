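# Example declarative run configuration for pipeline_run().
# Omitted fields fall back to default_run_config().
scenario: confounded_positive
n_participants: 1500
seed: 42
exposures:
  - dairy_total
link: identity
n_draws: 1000
out_dir: dietmsm_example_run
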