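parameter,intercept,log_membrane,log_turns
min,1.60,-1.02,2.76
peak,1.92,-1.01,2.26
max,2.22,-0.96,1.58
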