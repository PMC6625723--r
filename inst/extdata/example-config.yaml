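# Four-compartment hierarchy with the last dividing compartment leading
# (lambda0 = 0.42 at compartment 3) and a jumpwise de-differentiating mutant.
n: 4
r: [0.3, 0.4, 0.6]
p: [0.5, 0.65, 0.85]
# q defaults to 1 - p
d: 0.05
rho: 0.01
kappa: 1
mode: jumpwise
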