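[07:14:00] (+0.00s) poolacc 0.1.0 | command: no-such-command | seed: 1
[07:14:00] (+0.00s) options: --out=x
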