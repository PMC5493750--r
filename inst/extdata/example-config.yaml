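# Reference mingled-state run: strong repulsion at the standard density.
B: 5
H: 1
v0: 1
dt: 0.01
Lx: 84
Ly: 42
N: 494
seed: 1
steps: 30000
save_every: 300
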