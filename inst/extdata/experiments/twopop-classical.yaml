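# Two-population chimera at the classical parameters; one population
# synchronizes, the other stays incoherent and oscillates faster.
name: twopop-classical
model: twopop
parameters:
  rho: 5
duration: 1000
burn_in: 100
window: 1000
seed: 1
precession: true
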