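mz	intensity
839.5	100
483.2	80
374.5	30
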