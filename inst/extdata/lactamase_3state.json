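{
  "id": "lactamase_3state",
  "description": "Reversible three-state Michaelis-Menten cycle for class A beta-lactamase catalysis. Rate constants are not packaged (experimental values must be supplied by the user); binding (P1) and release (P3) steps are pseudo-first-order in substrate and product activity.",
  "states": [
    {"id": "E", "label": "free enzyme"},
    {"id": "ES", "label": "enzyme-substrate complex"},
    {"id": "EP", "label": "enzyme-product complex"}
  ],
  "transitions": [
    {"id": "P1", "from": "E", "to": "ES", "k_forward": null, "k_backward": null, "kind": "chemical", "role": "substrate_binding"},
    {"id": "P2", "from": "ES", "to": "EP", "k_forward": null, "k_backward": null, "kind": "chemical", "role": "acylation"},
    {"id": "P3", "from": "EP", "to": "E", "k_forward": null, "k_backward": null, "kind": "chemical", "role": "product_release"}
  ],
  "parameters": {
    "temperature_K": 298.16,
    "rate_constants": "REQUIRED-INPUT"
  },
  "temperature_K": 298.16
}
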