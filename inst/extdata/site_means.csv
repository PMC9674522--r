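site,medium,basis,unit,K40,U238,Th232
Beryllium,soil,in_situ,Bq/kg,412.99,19.83,20.62
Gold,soil,in_situ,Bq/kg,647.74,43.47,45.61
Beryllium,soil,lab,Bq/kg,509.74,12.82,16.63
Gold,soil,lab,Bq/kg,371.23,11.73,14.35
Beryllium,water,lab,Bq/L,23.65,0.8,1.03
Gold,water,lab,Bq/L,29.86,1,1.3
Beryllium,grain,lab,Bq/kg,105.85,2.19,5.22
Gold,grain,lab,Bq/kg,179.62,2.19,4.08
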