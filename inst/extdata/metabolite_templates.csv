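# Built-in 1H-NMR metabolite template library (synthetic spectrum generator).
# One row per Lorentzian line; multiplets are approximated by a few lines at
# standard reference chemical shifts (500 MHz conventions, TSP = 0 ppm).
# base_concentration is the dimensionless per-metabolite concentration used
# by the simulator for the control group; diagnostic marks the multiplet used
# for the default bin-to-metabolite annotation map (one region per
# metabolite, chosen to avoid cross-metabolite overlap).
name,base_concentration,center_ppm,relative_height,halfwidth_ppm,diagnostic
lactate,1.6,1.326,1.50,0.0025,1
lactate,1.6,1.340,1.50,0.0025,1
lactate,1.6,4.112,0.50,0.0030,0
alpha-glucose,1.2,5.229,0.50,0.0025,1
alpha-glucose,1.2,5.237,0.50,0.0025,1
alpha-glucose,1.2,3.700,1.00,0.0035,0
alpha-glucose,1.2,3.530,0.80,0.0035,0
beta-glucose,1.4,4.645,0.50,0.0025,1
beta-glucose,1.4,4.661,0.50,0.0025,1
beta-glucose,1.4,3.240,0.90,0.0035,0
creatine,1.0,3.030,3.00,0.0020,1
creatine,1.0,3.930,2.00,0.0025,0
taurine,1.1,3.426,2.00,0.0030,1
taurine,1.1,3.260,2.00,0.0030,0
nad,0.6,9.330,0.30,0.0030,1
nad,0.6,9.140,0.30,0.0030,0
nad,0.6,8.830,0.30,0.0030,0
nad,0.6,8.420,0.30,0.0030,0
allantoin,0.9,5.393,1.00,0.0030,1
nicotinate,0.7,8.610,0.40,0.0030,1
nicotinate,0.7,8.950,0.40,0.0030,0
nicotinate,0.7,8.250,0.40,0.0030,0
nicotinamide-n-oxide,0.7,8.770,0.40,0.0030,1
nicotinamide-n-oxide,0.7,8.450,0.40,0.0030,0
nicotinamide-n-oxide,0.7,8.180,0.40,0.0030,0
succinate,1.0,2.408,4.00,0.0020,1
acetone,0.8,2.230,6.00,0.0020,1
valine,0.9,0.989,1.50,0.0025,1
valine,0.9,1.003,1.50,0.0025,1
valine,0.9,1.034,1.50,0.0025,0
valine,0.9,1.048,1.50,0.0025,0
threonine,0.9,4.250,0.50,0.0030,1
threonine,0.9,1.318,1.20,0.0025,0
threonine,0.9,1.332,1.20,0.0025,0
formate,0.5,8.456,1.00,0.0020,1
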