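{
  "id": "br_8state",
  "description": "Eight-state kinetic model of the bacteriorhodopsin photocycle: ground state bR (1) and excited state bR* (2) joined by parallel light (L) and non-radiative decay (D) edges, and productive proton-transport transitions T1..T7 through the spectroscopic intermediates back to the ground state. Published parameters are pre-filled; T2..T6 rate constants and the effective radiation temperature T_R are REQUIRED-INPUT. K_1 follows from the secondary-force cycle closure.",
  "states": [
    {"id": "1", "label": "bR (ground)"},
    {"id": "2", "label": "bR* (excited)"},
    {"id": "3", "label": "K_590"},
    {"id": "4", "label": "L_550"},
    {"id": "5", "label": "M1_410"},
    {"id": "6", "label": "M2_410"},
    {"id": "7", "label": "N_560"},
    {"id": "8", "label": "O_640"}
  ],
  "transitions": [
    {"id": "L",  "from": "1", "to": "2", "k_forward": 100,    "K_eq": null, "kind": "light",        "role": "light_absorption"},
    {"id": "D",  "from": "1", "to": "2", "k_forward": null,   "K_eq": null, "kind": "nonradiative", "role": "nonradiative_decay", "k_backward": 1e8},
    {"id": "T1", "from": "2", "to": "3", "k_forward": 2.5e11, "K_eq": null, "kind": "chemical",     "role": "primary_relaxation (K_eq from cycle closure)"},
    {"id": "T2", "from": "3", "to": "4", "k_forward": null,   "K_eq": null, "kind": "chemical",     "role": "REQUIRED-INPUT"},
    {"id": "T3", "from": "4", "to": "5", "k_forward": null,   "K_eq": null, "kind": "chemical",     "role": "REQUIRED-INPUT"},
    {"id": "T4", "from": "5", "to": "6", "k_forward": null,   "K_eq": null, "kind": "chemical",     "role": "REQUIRED-INPUT"},
    {"id": "T5", "from": "6", "to": "7", "k_forward": null,   "K_eq": null, "kind": "chemical",     "role": "REQUIRED-INPUT"},
    {"id": "T6", "from": "7", "to": "8", "k_forward": null,   "K_eq": null, "kind": "chemical",     "role": "REQUIRED-INPUT"},
    {"id": "T7", "from": "8", "to": "1", "k_forward": 700,    "K_eq": 2e7,  "kind": "chemical",     "role": "recovery"}
  ],
  "parameters": {
    "temperature_K": 298.16,
    "lambda_nm": 570,
    "alpha01_per_s": 100,
    "k_d_per_s": 1e8,
    "k1_per_s": 2.5e11,
    "k1_note": "1/(4 ps) time constant",
    "k7_per_s": 700,
    "K7": 2e7,
    "T_R_K": "REQUIRED-INPUT",
    "X_sec_kJ_per_mol_columns": [-18.84, -26.86, -123],
    "membrane_potential_mV_columns": [-195, -278, -1185]
  },
  "temperature_K": 298.16
}
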