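{
  "tumor_transport": {
    "v_p": 0.23,
    "v_p_sd": 0.07,
    "v_e_av": 0.28,
    "v_e_av_sd": 0.13,
    "TT_s": 5.0,
    "TT_sd_s": 0.5,
    "PS_per_s": 0.012,
    "PS_sd_per_s": 0.005,
    "Hct_mv": 0.19,
    "F_p_per_s": 0.047,
    "EF": 0.22
  },
  "systemic_pk": {
    "V_D_mL": 8.99,
    "V_D_sd_mL": 0.58,
    "V_p_S_mL": 1.2,
    "k_p_per_s": 0.00129,
    "k_p_sd_per_s": 0.00052,
    "k_t_per_s": 0.00090,
    "k_t_sd_per_s": 0.00022,
    "k_e_per_s": 0.00080,
    "k_e_sd_per_s": 0.00030
  },
  "geometry": {
    "VT_mL": 0.00745341614906832
  },
  "dose": {
    "ID": 100,
    "form": "encapsulated"
  }
}
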