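id,molar_mass,measured
3PBA,214.2,TRUE
FPBA,232.2,TRUE
DBCA,298.0,TRUE
cis-DCCA,209.1,TRUE
trans-DCCA,209.1,TRUE
4OH-3PBA,230.2,FALSE
DCCA-gly,266.1,FALSE
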