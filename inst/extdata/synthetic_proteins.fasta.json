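{"synthetic_EtHv1_like":{"sf_position":62,"zinc_sites":[91,144],"synthetic":true},"synthetic_fungal_like":{"synthetic":true},"synthetic_sfD_variant":{"synthetic":true}}
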