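{
  "id": "atpase_5state",
  "description": "Five-state kinetic model of F0F1 ATP synthase: the open site cycles between empty (O:), nucleotide/phosphate-bound, and ATP-bound states. Two parallel two-step binding branches connect O: to O:P.ADP; transition M is ATP synthesis/hydrolysis and T is the ATP-release recovery step. Rate constants are not packaged and must be supplied by the user; reference observables are shipped in atpase_5state_observables.tsv.",
  "states": [
    {"id": "O", "label": "O: (empty open site)"},
    {"id": "OATP", "label": "O:ATP"},
    {"id": "OADP", "label": "O:ADP"},
    {"id": "OP", "label": "O:P"},
    {"id": "OPADP", "label": "O:P.ADP"}
  ],
  "transitions": [
    {"id": "T",  "from": "OATP",  "to": "O",     "k_forward": null, "k_backward": null, "kind": "chemical", "role": "recovery_ATP_release"},
    {"id": "M",  "from": "OPADP", "to": "OATP",  "k_forward": null, "k_backward": null, "kind": "chemical", "role": "synthesis_hydrolysis"},
    {"id": "DM", "from": "O",     "to": "OADP",  "k_forward": null, "k_backward": null, "kind": "chemical", "role": "binding_branch_major_1"},
    {"id": "PM", "from": "OADP",  "to": "OPADP", "k_forward": null, "k_backward": null, "kind": "chemical", "role": "binding_branch_major_2"},
    {"id": "PE", "from": "O",     "to": "OP",    "k_forward": null, "k_backward": null, "kind": "chemical", "role": "binding_branch_minor_1"},
    {"id": "DE", "from": "OP",    "to": "OPADP", "k_forward": null, "k_backward": null, "kind": "chemical", "role": "binding_branch_minor_2"}
  ],
  "parameters": {
    "temperature_K": 298.16,
    "rate_constants": "REQUIRED-INPUT"
  },
  "temperature_K": 298.16
}
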