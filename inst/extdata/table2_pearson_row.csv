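compartment,r_printed,p_printed
nodal,0.95,4e-10
osseous,0.38,0.09
prostate_bed,-0.06,Not calculated
composite,0.61,5e-4
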