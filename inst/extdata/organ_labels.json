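{
  "description": "Integer labels used in the organ-mask NIfTI volume. 0 = background.",
  "labels": {
    "1": "liver",
    "2": "blood_pool",
    "3": "prostate_bed",
    "4": "skeleton",
    "5": "nodal_region"
  }
}
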