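# Example configuration: desk-scale profile with a 45% vascular fraction.
# Any field of default_config() can be overridden here; unknown keys error.
profile: scaled
seed: 42
cells:
  vascular_fraction: 0.45
flow:
  delta_P: 1000
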