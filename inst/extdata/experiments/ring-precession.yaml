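# Ring chimera in the phase-precession regime: the mean-phase-velocity
# ratio between synchronized and unsynchronized domains sits near the
# hippocampal 8:9 Hz ratio (~0.88) at this intrinsic frequency.
name: ring-precession
model: ring
parameters:
  rho: 2.8
duration: 1000
burn_in: 100
window: 1000
seed: 1
precession: true
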