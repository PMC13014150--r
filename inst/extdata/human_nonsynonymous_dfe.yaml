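# Gamma DFE of deleterious non-synonymous mutations, on the population-scaled
# 2Ne*s axis; rescale with dfe_rescale() to obtain per-copy selection
# coefficients.
family: pop_gamma
shape: 0.169
scale: 1327.4
two_ne: 23646
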