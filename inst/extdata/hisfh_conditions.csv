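label,p_active,p_sd,kcat,kcat_sd,note
ProFAR,0.78,0.03,63,NA,reference condition (WT HisF with ProFAR and Gln)
ImGP,0.36,0.02,14,NA,
AICAR,0.04,0.02,1,NA,
fK19A,0.52,0.01,20,NA,
fV48A,0.32,0.01,7,NA,
fF23A,0.07,0.01,3,NA,
fD98E,0.99,NA,179,NA,equilibrium shifted fully active; 0.99 is an encoding convention
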