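# Two substrates converting reversibly into two products under a
# generative model that places mass alpha on "both substrates present"
# and 1 - alpha on "both products present". With alpha = 1/4 and the
# substrates initially at their maximum, the mean-field kinetics settle at
# a quarter of maximal substrate concentration, free energy falling to 0.
schema: catflow/1
kind: reaction_model
name: pair-reaction
alpha: 0.25
n_substrates: 2
n_products: 2
lambda: 1.0
corrected: true
initial:
  S1: 1.0
  S2: 1.0
  S3: 0.0
  S4: 0.0
simulation:
  t_start: 0.0
  t_end: 80.0
  n_steps: 321
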