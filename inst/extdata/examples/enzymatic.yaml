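# Open enzymatic reaction S + E <-> C <-> P + E with constant production
# of substrate and removal of product at rate c (a non-equilibrium steady
# state). Substrate starts with the system's whole convertible pool, the
# enzyme entirely free. Rate constants derive from the model parameters
# (see table2_constants).
schema: catflow/1
kind: enzymatic
name: enzymatic
alpha1: 0.2
alpha2: 0.5
z: 0.9
c: 0.05
lambda: 1.0
scale:
  n_max: 1.0
  volume: 1.0
initial:
  S: 1.0
  E: 1.0
  C: 0.0
  P: 0.0
simulation:
  t_start: 0.0
  t_end: 300.0
  n_steps: 1201
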