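source,channel,energy_keV
Cs-137,236,662
Co-60,408,1173
Co-60,461,1332
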