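V0_LH: 146.5792645
V1_LH: 775052.4760487
Km_LH: 486.8455251
Ki_LH_P: 63.5123161
k_LH: 2.7981542
c_LH_P: 1.8911558
c_LH_E: 0.0003933
alpha_LH: 4.5930732
V_FSH: 1343.8217638
Ki_FSH_Inh: 97.7444542
tau: 0.6977208
k_FSH: 1522.9784045
c_FSH_P: 378.7427798
c_FSH_E: 0.0005078
alpha_FSH: 22.6989826
v: 2.5
w: 2.5
q: 2.0
b: 0.0029424
c1: 0.0666255
c2: 0.0633612
c3: 0.2907645
c4: 0.005496
d1: 0.7882051
d2: 0.856645
k1: 0.9316551
k2: 1.7940437
k3: 0.9224801
k4: 1.7720923
alpha: 0.7751312
gamma: 1.4885049
e0: 1.0e-12
e1: 4.4404205e-11
e2: 0.2130253
e3: 0.0414524
p0: 1.0e-12
p1: 2.8205724e-11
p2: 0.046396
h0: 0.6369042
h1: 0.0025776
h2: 1.6209146e-10
h3: 0.0121713
b1: 1.0
b2: 1.0
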