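id	name
10	straight-seed
11	straight-target
20	arc-seed
21	arc-target
30	scurve-seed
31	scurve-target
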