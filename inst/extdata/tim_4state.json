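{
  "id": "tim_4state",
  "description": "Reversible four-state cycle for triosephosphate isomerase (DHAP -> GAP isomerization) with the transition-state intermediate EZ. Rate constants are not packaged and must be supplied by the user.",
  "states": [
    {"id": "E", "label": "free enzyme"},
    {"id": "ES", "label": "enzyme-DHAP complex"},
    {"id": "EZ", "label": "enediol intermediate complex"},
    {"id": "EP", "label": "enzyme-GAP complex"}
  ],
  "transitions": [
    {"id": "P1", "from": "E", "to": "ES", "k_forward": null, "k_backward": null, "kind": "chemical", "role": "substrate_binding"},
    {"id": "P2", "from": "ES", "to": "EZ", "k_forward": null, "k_backward": null, "kind": "chemical", "role": "proton_transfer_1"},
    {"id": "P3", "from": "EZ", "to": "EP", "k_forward": null, "k_backward": null, "kind": "chemical", "role": "proton_transfer_2"},
    {"id": "P4", "from": "EP", "to": "E", "k_forward": null, "k_backward": null, "kind": "chemical", "role": "product_release"}
  ],
  "parameters": {
    "temperature_K": 298.16,
    "rate_constants": "REQUIRED-INPUT"
  },
  "temperature_K": 298.16
}
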