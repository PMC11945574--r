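compound,metabolite,phi
deltamethrin,DBCA,0.43
deltamethrin,3PBA,0.19
deltamethrin,4OH-3PBA,0.05
cis-permethrin,cis-DCCA,0.30
cis-permethrin,3PBA,0.25
cis-permethrin,4OH-3PBA,0.07
trans-permethrin,trans-DCCA,0.52
trans-permethrin,3PBA,0.35
trans-permethrin,4OH-3PBA,0.07
cis-cypermethrin,cis-DCCA,0.31
cis-cypermethrin,3PBA,0.24
cis-cypermethrin,4OH-3PBA,0.06
trans-cypermethrin,trans-DCCA,0.50
trans-cypermethrin,3PBA,0.33
trans-cypermethrin,4OH-3PBA,0.06
cis-cyfluthrin,cis-DCCA,0.28
cis-cyfluthrin,FPBA,0.22
trans-cyfluthrin,trans-DCCA,0.48
trans-cyfluthrin,FPBA,0.30
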