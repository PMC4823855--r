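algorithm,reference,n_total,n_ref_pos,n_code_pos,sn,sn_lo,sn_hi,sp,sp_lo,sp_hi,ppv,ppv_lo,ppv_hi,npv,npv_lo,npv_hi,lr_plus
any_diagnosis,stage_ge1,524,236,74,28.0,22.6,34.0,97.2,94.6,98.6,89.2,80.1,94.4,62.2,57.7,66.6,10.0
any_diagnosis,stage_ge2,524,76,74,42.1,31.7,53.3,90.6,87.6,93.0,43.2,32.6,54.6,90.2,87.1,92.6,4.5
any_diagnosis,stage_eq3,524,55,74,40.0,28.1,53.2,88.9,85.8,91.4,29.7,20.5,40.9,92.7,89.9,94.7,3.6
admission_diagnosis,stage_ge1,524,236,54,20.3,15.7,25.9,97.9,95.5,99.0,88.9,77.8,94.8,60.0,55.5,64.3,9.7
admission_diagnosis,stage_ge2,524,76,54,34.2,24.5,45.4,93.8,91.1,95.6,48.2,35.4,61.2,89.4,86.3,91.8,5.5
admission_diagnosis,stage_eq3,524,55,54,32.7,21.8,45.9,92.3,89.6,94.4,33.3,22.2,46.6,92.1,89.3,94.2,4.2
main_diagnosis,stage_ge2,524,76,25,17.1,10.3,27.1,97.3,95.4,98.5,52.0,33.5,70.0,87.4,84.2,90.0,6.3
main_diagnosis,stage_eq3,524,55,25,18.2,10.2,30.3,96.8,94.8,98.1,40.0,23.4,59.3,91.0,88.2,93.2,5.7
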