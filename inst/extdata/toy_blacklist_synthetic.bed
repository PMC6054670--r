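chr2	1500000	1506000	lowmap
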