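month,tmax,tmin,rain,sr,snh
Aug,23.9,16.1,180.4,12.7,12.2
Sep,24.1,16.3,41.4,11.1,12.1
Oct,20.9,11.4,89.4,12.9,11.4
Nov,19.22,8.6,15.8,13.1,10.8
Dec,13.7,5.1,35.4,8.9,10.5
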