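# Pair of coupled reversible reactions S1 + S2 <-> S3 <-> S4 + S5 sharing
# the intermediate S3. Rate constants derive from the generative-model
# parameters (see table1_constants); the marginal of S1, plus S3, plus S4
# is conserved at one.
schema: catflow/1
kind: coupled_reactions
name: coupled-reactions
alpha1: 0.2
alpha2: 0.5
z: 0.5
lambda: 1.0
initial:
  S1: 1.0
  S2: 1.0
  S3: 0.0
  S4: 0.0
  S5: 0.0
simulation:
  t_start: 0.0
  t_end: 120.0
  n_steps: 481
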