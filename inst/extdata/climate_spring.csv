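month,tmax,tmin,rain,sr,snh
Mar,19.5,10.5,14.2,19.8,11.8
Apr,21.8,11.8,21.4,20.5,12.6
May,21.3,10.2,128,19.8,13.3
Jun,19.6,12.6,236.2,13.3,13.6
Jul,20.3,12.3,354.4,14.3,13.4
Aug,19.4,12.1,150.2,15.2,12.9
Sep,20.1,11.3,244.8,17.5,12.1
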