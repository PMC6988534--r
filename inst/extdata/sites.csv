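population,elevation_m,lat,lon,life_zone,mat_c,season_days
RF_CM,1577,40.061,-105.193,High plains,10.67,199.8
A1,2195,40.015,-105.377,Lower montane,7.93,164.5
B1,2591,40.023,-105.430,Upper montane,5.98,148.0
C1,3048,40.036,-105.547,Subalpine,1.79,100.5
D1,3515,40.059,-105.617,Alpine,-3.50,84.4
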