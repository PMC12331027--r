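season,genotype,wmax,tm,te,a_max,tu,b,rue,reported_yield,emergence_day,maturity_day
spring,Yunshu 401,1,243,1145,0.88,988,426,5.5,138,47,170
spring,Yunshu 505,0.99,99,1107,1,1044,473,4.4,147,44,164
spring,Cooperation 88,1,427,1304,0.89,1258,394,3.98,91.9,42,184
autumn,Yunshu 401,0.77,482,1040,0.96,669,290,2.9,35.23,21,107
autumn,Yunshu 505,1,341,1014,0.91,721,250,2.8,46.67,25,120
autumn,Cooperation 88,1,524,1028,0.87,823,190,3.7,53.95,16,116
early_spring,Yunshu 401,0.7742,200.1,956.4,0.9249,544,150.1,2.8,53.03,34,123
early_spring,Yunshu 505,0.83,112.7,898.5,0.99,545.8,186.5,2.63,62.78,32,121
early_spring,Cooperation 88,0.8,262,946,1,532,386,2.7,53.48,35,122
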