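{
  "v_names": ["V", "E", "membrane_voltage", "Vm", "v", "V_m"],
  "cm_names": ["Cm", "C_m", "C_sc", "C", "C_memb", "Cap"],
  "stim_names": ["i_Stim", "I_st", "i_stim", "I_stim", "i_st", "IStim", "i_pulse", "i_app"],
  "time_names": ["time", "t", "T"]
}
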