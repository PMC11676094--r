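# Serum xanthine oxidoreductase (XOR, assayed with NAD+) and xanthine
# oxidase (XO, assayed without NAD+) activities in U/mL for the acute
# restraint-stress rat experiment. Xanthine dehydrogenase (XDH) activity is
# derived as XOR minus XO.
group,xor_mean,xor_sd,xo_mean,xo_sd,n
nonstressed,0.802,0.099,0.556,0.091,6
stressed,0.694,0.079,0.523,0.081,7
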