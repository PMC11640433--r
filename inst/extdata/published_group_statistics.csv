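group,density,mean_sri,sri_sd
West,0.590,0.032,0.056
East,0.733,0.022,0.040
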