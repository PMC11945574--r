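id,molar_mass,parent_group,isomer_fraction
deltamethrin,505.2,deltamethrin,1.0
cis-permethrin,391.3,permethrin,0.4
trans-permethrin,391.3,permethrin,0.6
cis-cypermethrin,416.3,cypermethrin,0.4
trans-cypermethrin,416.3,cypermethrin,0.6
cis-cyfluthrin,434.3,cyfluthrin,0.4
trans-cyfluthrin,434.3,cyfluthrin,0.6
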