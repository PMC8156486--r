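# Three-state master equation with a non-trivial solenoidal component.
# Use mode: solenoidal / dissipative to integrate the decomposed flows.
schema: catflow/1
kind: rate_matrix
name: threestate
labels: [s1, s2, s3]
rows:
- [-3.0, 1.0, 2.0]
- [2.0, -2.0, 1.0]
- [1.0, 1.0, -3.0]
initial:
  s1: 1.0
  s2: 0.0
  s3: 0.0
simulation:
  t_start: 0.0
  t_end: 10.0
  n_steps: 201
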