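2026-09-25 07:29:30 rbfspls 0.1.0 command: bogus
2026-09-25 07:29:59 rbfspls 0.1.0 command: bogus
2026-09-25 07:40:38 rbfspls 0.1.0 command: bogus
2026-09-25 08:01:37 rbfspls 0.1.0 command: bogus
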