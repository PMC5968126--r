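# Courtemanche-Ramirez-Nattel human atrial myocyte model: versioned constant
# record used by the implementation.  Conductances in nS/pF, concentrations in
# mM, volumes in um^3, capacitance in pF, temperatures in K.
physical:
  R: 8.3143
  T: 310.0
  F: 96.4867
cell:
  Cm: 100.0
  V_i: 13668.0
  V_up: 1109.52
  V_rel: 96.48
external:
  K_o: 5.4
  Na_o: 140.0
  Ca_o: 1.8
conductances:
  g_Na: 7.8
  g_K1: 0.09
  g_to: 0.1652
  g_Kr: 0.029411765
  g_Ks: 0.12941176
  g_CaL: 0.12375
  g_bCa: 0.001131
  g_bNa: 0.0006744375
pumps_exchangers:
  I_NaK_max: 0.59933874
  Km_Nai: 10.0
  Km_Ko: 1.5
  I_NaCa_max: 1600.0
  Km_Na: 87.5
  Km_Ca: 1.38
  k_sat: 0.1
  gamma: 0.35
  I_pCa_max: 0.275
calcium_handling:
  k_rel: 30.0
  I_up_max: 0.005
  K_up: 0.00092
  Ca_up_max: 15.0
  tau_tr: 180.0
  tau_fca: 2.0
  tau_u: 8.0
buffers:
  CMDN_max: 0.05
  TRPN_max: 0.07
  CSQN_max: 10.0
  Km_Cmdn: 0.00238
  Km_Trpn: 0.0005
  Km_Csqn: 0.8
kinetics:
  K_Q10: 3.0
initial_state:
  V: -81.18
  m: 2.908e-3
  h: 9.649e-1
  j: 9.775e-1
  oa: 3.043e-2
  oi: 9.992e-1
  ua: 4.966e-3
  ui: 9.986e-1
  xr: 3.296e-5
  xs: 1.869e-2
  d: 1.367e-4
  f: 9.996e-1
  fca: 7.755e-1
  u: 0.0
  v: 1.0
  w: 9.992e-1
  Na_i: 11.17
  K_i: 139.0
  Ca_i: 1.013e-4
  Ca_up: 1.488
  Ca_rel: 1.488
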