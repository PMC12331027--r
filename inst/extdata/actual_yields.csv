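season,actual_yield
spring,19.6
autumn,15.27
early_spring,20.72
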