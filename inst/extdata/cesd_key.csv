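item,reverse
cesd_4,TRUE
cesd_8,TRUE
cesd_12,TRUE
cesd_16,TRUE
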