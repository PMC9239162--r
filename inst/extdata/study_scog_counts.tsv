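metric	count
total_scogs	3942
expressed_scogs	3864
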