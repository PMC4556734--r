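node_id
49
59
93
179
209
237
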