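# Reference parameter set of the bistable phage-bacterium ecosystem.
# Bistable for nutrient supply rates 0.2267 < phi < 0.7.
lambda1: 1.0
lambda2: 0.8
Y1: 1.0
Y2: 1.0
eta1: 0.2
eta2: 0.15
beta1: 2.0
beta2: 40.0
deltaC: 0.2
deltaB: 0.2
deltaP: 0.2
phi: 0.66
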