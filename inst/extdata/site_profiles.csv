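site,medium,basis,nuclide,mean,sd,min,max,skewness,n_samples,unit
Beryllium,soil,in_situ,U238,19.83,17.09,1.24,65.46,0.79,24,Bq/kg
Beryllium,soil,in_situ,K40,412.99,250.83,93.9,1001.6,0.89,24,Bq/kg
Beryllium,soil,in_situ,Th232,20.62,10.62,5.68,41.01,0.27,24,Bq/kg
Gold,soil,in_situ,U238,43.47,23.89,3.71,97.57,0.16,24,Bq/kg
Gold,soil,in_situ,K40,647.74,152.94,406.9,970.3,0.48,24,Bq/kg
Gold,soil,in_situ,Th232,45.61,13.91,11.37,73.89,-0.33,24,Bq/kg
Beryllium,soil,lab,U238,12.82,8.19,3.51,18.94,-1.48,24,Bq/kg
Beryllium,soil,lab,K40,509.74,353.73,120.19,810.88,-1.05,24,Bq/kg
Beryllium,soil,lab,Th232,16.63,10.02,5.29,24.29,-1.43,24,Bq/kg
Gold,soil,lab,U238,11.73,0.51,10.72,11.73,-0.03,24,Bq/kg
Gold,soil,lab,K40,371.23,39.82,327.38,405.14,-1.05,24,Bq/kg
Gold,soil,lab,Th232,14.35,0.29,13.78,14.35,-0.85,24,Bq/kg
Beryllium,water,lab,U238,0.8,0.39,0.35,1.06,0,12,Bq/L
Beryllium,water,lab,K40,23.65,10.75,11.27,30.67,0,12,Bq/L
Beryllium,water,lab,Th232,1.03,0.45,0.51,1.3,0,12,Bq/L
Gold,water,lab,U238,1,0.19,0.83,1.21,0,12,Bq/L
Gold,water,lab,K40,29.86,5.29,25.93,35.87,0,12,Bq/L
Gold,water,lab,Th232,1.3,0.23,1.16,1.56,0,12,Bq/L
Beryllium,grain,lab,U238,2.19,0.41,1.72,2.43,0,24,Bq/kg
Beryllium,grain,lab,K40,105.85,7.25,97.48,110.03,0,24,Bq/kg
Beryllium,grain,lab,Th232,5.22,0.05,5.17,5.25,0,24,Bq/kg
Gold,grain,lab,U238,2.19,1.3,0.18,4.7,0,24,Bq/kg
Gold,grain,lab,K40,179.62,134.43,24.39,257.23,0,24,Bq/kg
Gold,grain,lab,Th232,4.08,2.87,2.39,7.39,0,24,Bq/kg
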