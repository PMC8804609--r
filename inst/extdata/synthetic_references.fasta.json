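{"synthetic_hHv1_like_ref":{"sf_position":112,"zinc_sites":[140,193],"synthetic":true},"synthetic_NpHv1_like_ref":{"sf_position":66,"synthetic":true}}
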