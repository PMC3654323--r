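subscale_id,kappa,chi_square,sensitivity_pct,specificity_pct,ppv_pct,npv_pct,n
kidney_deficiency,0.273,63.9,65.9,71.2,65.2,72.6,171
spleen_deficiency,0.248,125.5,58.1,92.8,47.3,84.8,171
qi_deficiency,0.538,50.9,58.8,91.7,75.0,84.0,171
yin_deficiency,0.699,87.7,68.3,97.3,93.2,85.0,171
yang_deficiency,0.591,86.8,63.8,92.3,76.0,84.7,171
marrow_deficiency,0.621,66.7,63.6,94.9,75.0,91.6,171
yang_hyperactivity,0.685,84.4,90.5,92.0,61.3,98.6,171
endogenous_heat,0.492,44.2,72.7,87.9,47.1,95.6,171
phlegm_muddiness,0.663,75.6,83.5,83.8,88.7,77.0,171
blood_stasis,0.790,108.0,94.7,85.3,83.7,95.3,171
blood_deficiency,0.547,73.913,71.428,92.4,75.1,84.1,171
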