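rates:
  k_bind_flavin: 5.0
  k_inact: 0.41
  k_ox: 0.1290625
  k_unc: 0.41
  k_dehyd: 0.073
  k_capture: 37.5
  k_leak: 62.5
  f_unc_pop: ~
halides:
  I:
    Kd_mM: 0.064
    k_hox_s1: 4.51
    E_TS_kcal_mol: 1.3
    E_product_kcal_mol: -51.799999999999997
  Br:
    Kd_mM: 0.4
    k_hox_s1: 2.54
    E_TS_kcal_mol: 5.7
    E_product_kcal_mol: -39.799999999999997
  Cl:
    Kd_mM: 0.78
    k_hox_s1: 1.83
    E_TS_kcal_mol: 12.6
    E_product_kcal_mol: -28.5
initial:
  E_free: 15.0
  E_FADH: 15.0
  O2_uM: 128.0
  X_conc_mM: 10.0
optics:
  path_length_cm: 1.0
  eps:
    FADH:
      A380: 3.0
      A450: 0.7
    C4aOOH:
      A380: 8.0
      A450: 0.8
    C4aOH:
      A380: 7.5
      A450: 0.8
    FAD:
      A380: 6.0
      A450: 11.300000000000001
    none:
      A380: 0.0
      A450: 0.0
  phi:
    FADH:
      F_ex380: 0.02
      F_ex450: 0.02
    C4aOOH:
      F_ex380: 0.02
      F_ex450: 0.02
    C4aOH:
      F_ex380: 1.0
      F_ex450: 0.3
    FAD:
      F_ex380: 0.02
      F_ex450: 0.02
    none:
      F_ex380: 0.0
      F_ex450: 0.0
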