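name,side,proximal_idx,distal_idx,mass_fraction_male,mass_fraction_female,k_male,k_female
trunk,mid,8,1,0.551,0.532,0.630,0.569
head_neck,mid,1,0,0.0826,0.0820,0.550,0.550
upper_arm_r,right,2,3,0.0325,0.0290,0.436,0.458
upper_arm_l,left,5,6,0.0325,0.0290,0.436,0.458
forearm_r,right,3,4,0.0187,0.0157,0.430,0.434
forearm_l,left,6,7,0.0187,0.0157,0.430,0.434
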