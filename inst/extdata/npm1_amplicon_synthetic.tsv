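key	value
hotspot_start	105
hotspot_end	135
coding_offset	753
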