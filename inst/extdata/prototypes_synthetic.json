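{"k":4,"selected":[3,4,1,2],"coverage":1}
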