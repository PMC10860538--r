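antibody,is_isotype
CD1c,FALSE
CD2,FALSE
CD3,FALSE
CD4,FALSE
CD5,FALSE
CD7,FALSE
CD8,FALSE
CD10,FALSE
CD11b,FALSE
CD11c,FALSE
CD13,FALSE
CD14,FALSE
CD16,FALSE
CD19,FALSE
CD22,FALSE
CD25,FALSE
CD26,FALSE
CD30,FALSE
CD32,FALSE
CD33,FALSE
CD34,FALSE
CD38,FALSE
CD42b,FALSE
CD45,FALSE
CD45RA,FALSE
CD49d,FALSE
CD56,FALSE
CD62P,FALSE
CD64,FALSE
CD69,FALSE
CD71,FALSE
CD83,FALSE
CD90,FALSE
CD117,FALSE
CD123,FALSE
CD138,FALSE
CD141,FALSE
CD163,FALSE
CD303,FALSE
CD304,FALSE
HLA-DR,FALSE
FCER1A,FALSE
IgG1_iso,TRUE
IgG2a_iso,TRUE
IgG2b_iso,TRUE
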