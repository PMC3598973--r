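parameter,intercept,log_membrane,log_turns
min,1.66,-0.89,2.25
peak,1.88,-0.88,2.00
max,2.09,-0.78,1.44
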