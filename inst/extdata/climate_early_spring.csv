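month,tmax,tmin,rain,sr,snh
Jan,14.5,1.2,72.5,23.7,13.4
Feb,18.7,3.2,5.2,15.74,12.9
Mar,24.6,8.5,26,19.3,12.1
Apr,23,10.6,70.8,16.9,11.4
May,27.6,13.9,15.6,20,10.8
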