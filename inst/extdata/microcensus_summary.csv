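dataset,type,n_locations,mean_sample_area_ha,total_area_ha,mean_density
DS1,Overall,100,3.16,315.74,245.2
DS1,A,1,0.82,0.82,843.0
DS1,B,15,2.74,41.13,281.7
DS1,C,3,2.89,8.67,249.3
DS1,D,6,4.50,26.98,136.0
DS1,E,0,NA,0.00,NA
DS1,F,3,8.53,25.59,58.0
DS1,M,72,2.95,212.54,246.0
DS2,Overall,67,2.55,170.73,321.6
DS2,A,12,1.38,16.51,617.3
DS2,B,12,1.64,19.69,405.3
DS2,C,12,2.42,29.00,307.5
DS2,D,13,3.08,40.09,159.7
DS2,E,7,1.22,8.51,401.3
DS2,F,11,5.18,56.94,63.7
DS2,M,0,NA,0.00,NA
Combined,Overall,167,2.91,486.47,275.8
Combined,A,13,1.33,17.33,634.6
Combined,B,27,2.25,60.82,336.6
Combined,C,15,2.51,37.67,295.9
Combined,D,19,3.53,67.07,152.2
Combined,E,7,1.22,8.51,401.3
Combined,F,14,5.89,82.53,62.5
Combined,M,72,2.95,212.54,246.0
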