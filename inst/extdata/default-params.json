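{
  "time": {
    "dt_ms": 0.5
  },
  "plant": {
    "theta_rest": 70,
    "inertia": 8,
    "damping": 8,
    "stiffness": 1,
    "eps_contact_deg": 2,
    "k_contact": 4,
    "b_contact": 5
  },
  "cpg": {
    "cycle_duration_ms": 5,
    "ExtP": {
      "cycles_num": 7,
      "silence_ms": 115,
      "offset_ms": 0
    },
    "Int": {
      "cycles_num": 12,
      "silence_ms": 90,
      "offset_ms": 25
    },
    "ExtR": {
      "cycles_num": 13,
      "silence_ms": 85,
      "offset_ms": 83
    }
  },
  "neuron": {
    "t_relay_ms": 1,
    "arp_ms": 2,
    "rrp_ms": 20,
    "t_integ_ms": 4,
    "threshold": 1,
    "rrp_factor": 1.1,
    "w_cpg_solo": 1.7,
    "w_cpg_coinc": 0.6,
    "rrp_factor_extr": 2,
    "rrp_ms_extr": 12,
    "w_sn2w_coinc": 0.2,
    "cap_sn2w_coinc": 0.55,
    "w_sn2w_solo": 0.6,
    "sn2_volley_frac": 0.4,
    "sn2_arp_ms": 2,
    "sn2_w_min_sources": 2,
    "tip_w": 0.12,
    "tip_threshold": 1.5,
    "tip_window_ms": 30,
    "tip_burst_n": 1,
    "tip_burst_gap_ms": 2.5,
    "veto_direct_ms": 18,
    "veto_indirect_ms": 20,
    "veto_fraction": 1,
    "inhib_extra_delay_ms": 0
  },
  "afferent": {
    "pressure_latency_at_r0_ms": 15.7,
    "pressure_latency_slope_ms": 16,
    "pressure_latency_r0": 0.4,
    "pressure_interval_ms": 13.5,
    "sn1_relay_ms": 0.5,
    "sn2_relay_ms": 1,
    "w_spikes_per_protraction": 4,
    "w_interval_ms": 18,
    "w_spont_hz": 6,
    "omega_min_deg_ms": 0.02
  },
  "pools": {
    "sn1_w": 73,
    "sn1_c": 33,
    "sn1_p": 28,
    "sn1_d": 28,
    "sn2_per_subtype": 10,
    "mn_per_type": 10,
    "sn2_fanin_frac": 0.5
  },
  "muscle": {
    "share_rostral": 0.818181818181818,
    "intrinsic": {
      "ca_gain": 1,
      "tau_ms": 12,
      "ca0": 1.25,
      "ca_sat": 0.5,
      "a_max": 6.05
    },
    "pseudo_intrinsic": {
      "ca_gain": 1,
      "tau_ms": 12,
      "ca0": 1.25,
      "ca_sat": 0.5,
      "a_max": 6.05
    },
    "extP": {
      "ca_gain": 1,
      "tau_ms": 12,
      "ca0": 0.5,
      "ca_sat": 1,
      "a_max": 4.85
    },
    "extR_sup": {
      "ca_gain": 2.4,
      "tau_ms": 4,
      "ca0": 0.12,
      "ca_sat": 6,
      "a_max": 18,
      "ca_max": 2.6
    },
    "extR_deep": {
      "ca_gain": 0.9,
      "tau_ms": 30,
      "ca0": 0.3,
      "ca_sat": 1,
      "a_max": 1.15,
      "ca_max": 4
    }
  }
}
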