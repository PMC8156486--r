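# Seven-species Michaelis-Menten network: an external source feeds the
# sensory species S3, mass flows S3 -> S2 -> S1 and then down two branches
# S1 -> S4 -> S5 and S1 -> S6 -> S7, with saturating efflux from the
# active species S5 and S7. Interior conversions have weaker reverse
# reactions so that perturbations propagate upstream as well as down.
# Lesion the S1_to_S4 reaction (lesions: [S1_to_S4]) to reproduce a
# diaschisis: loss of S4 and S5 with compensatory increases in S2 and S6.
schema: catflow/1
kind: network
name: metabolic
species: [S1, S2, S3, S4, S5, S6, S7]
sources:
  S3: 0.1
reactions:
- {id: S3_to_S2, type: michaelis_menten, substrate: S3, product: S2, v_max: 1.0, kappa_m: 1.0}
- {id: S2_to_S1, type: michaelis_menten, substrate: S2, product: S1, v_max: 1.0, kappa_m: 1.0}
- {id: S1_to_S4, type: michaelis_menten, substrate: S1, product: S4, v_max: 1.0, kappa_m: 1.0}
- {id: S4_to_S5, type: michaelis_menten, substrate: S4, product: S5, v_max: 1.0, kappa_m: 1.0}
- {id: S1_to_S6, type: michaelis_menten, substrate: S1, product: S6, v_max: 1.0, kappa_m: 1.0}
- {id: S6_to_S7, type: michaelis_menten, substrate: S6, product: S7, v_max: 1.0, kappa_m: 1.0}
- {id: S2_to_S3, type: michaelis_menten, substrate: S2, product: S3, v_max: 0.5, kappa_m: 1.0}
- {id: S1_to_S2, type: michaelis_menten, substrate: S1, product: S2, v_max: 0.5, kappa_m: 1.0}
- {id: S4_to_S1, type: michaelis_menten, substrate: S4, product: S1, v_max: 0.5, kappa_m: 1.0}
- {id: S5_to_S4, type: michaelis_menten, substrate: S5, product: S4, v_max: 0.5, kappa_m: 1.0}
- {id: S6_to_S1, type: michaelis_menten, substrate: S6, product: S1, v_max: 0.5, kappa_m: 1.0}
- {id: S7_to_S6, type: michaelis_menten, substrate: S7, product: S6, v_max: 0.5, kappa_m: 1.0}
- {id: S5_out, type: michaelis_menten, substrate: S5, v_max: 1.0, kappa_m: 1.0}
- {id: S7_out, type: michaelis_menten, substrate: S7, v_max: 1.0, kappa_m: 1.0}
initial:
  S1: 0.0
  S2: 0.0
  S3: 0.0
  S4: 0.0
  S5: 0.0
  S6: 0.0
  S7: 0.0
simulation:
  t_start: 0.0
  t_end: 200.0
  n_steps: 401
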