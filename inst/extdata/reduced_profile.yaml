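N_m: 1000
N_v: 560
sigma_nm: 30.0
T_K: 293.0
k_chrom: 15.0
eps_chrom: 5.0
k_bend_max: 23.2079442
k_memb: 2500.0
R_round: 50.0
f: 0.1
R: 10.7721735
d_nucleation: 2.3207944
N_spread: 10
F_max: 92831.7766723
twist_total: 31.4159265
bulk_cut: 0.85
gamma: 1.0
dt: 0.005
seed: 1
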