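# MacCannell et al. active fibroblast model: versioned constant record.
# Exactly four membrane currents: I_Kv (time- and voltage-dependent K),
# I_K1 (inward rectifier K), I_NaK (Na-K pump), I_bNa (background Na).
# Conductances in nS/pF, concentrations in mM, capacitance in pF.
cell:
  Cm_fb: 6.3
concentrations:
  K_o: 5.3581
  K_i: 129.4349
  Na_o: 130.0110
  Na_i: 8.5547
I_Kv:
  g_Kv: 0.25
I_K1:
  g_K1: 0.4822
I_NaK:
  I_NaK_max: 2.002
  Km_K: 1.0
  Km_Na: 11.0
  V_rev: -150.0
  B: -200.0
I_bNa:
  g_bNa: 0.0095
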