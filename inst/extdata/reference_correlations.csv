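# Discriminating-metabolite correlation coefficients (OPLS-DA predictive
# score vs binned intensity) reported for the acute restraint-stress rat
# experiment this package models: 6 non-stressed vs 7 stressed animals,
# pairwise comparisons of stressed (24 h or 48 h post-stress) against
# non-stressed controls per biological matrix. Positive r = elevated in the
# stressed group. Only entries exceeding the |r| > 0.755 significance cutoff
# were reported.
metabolite,comparison,r
acetone,urine_24h,-0.774
adenosine,lung,0.773
allantoic acid,lung,-0.815
allantoin,brain,-0.846
allantoin,liver,-0.758
alpha-glucose,brain,-0.795
alpha-glucose,plasma,-0.904
beta-glucose,plasma,-0.871
creatine,brain,0.868
creatinine,brain,0.795
ethanolamine,kidney,0.762
gamma-aminobutyrate,brain,0.766
glutamate,brain,0.797
glutamate,liver,-0.774
glycerophosphocholine,brain,-0.791
glycogen,brain,-0.791
guanosine,liver,-0.832
guanosine,lung,0.830
lactate,brain,0.862
lactate,plasma,0.907
leucine,brain,-0.803
n-acetylaspartate,brain,0.901
nad,brain,-0.767
nad,liver,-0.834
nadp,liver,-0.822
nicotinamide-n-oxide,urine_24h,0.767
nicotinate,urine_24h,0.839
pantothenate,kidney,0.851
phosphocholine,brain,-0.796
phosphoethanolamine,brain,-0.882
succinate,urine_48h,-0.806
taurine,brain,-0.797
threonine,brain,-0.771
tyrosine,kidney,0.791
uracil,kidney,0.786
valine,brain,-0.791
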