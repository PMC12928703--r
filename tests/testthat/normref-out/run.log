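[normref 08:44:32] done in 0.0s
[normref 08:47:38] done in 0.0s
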