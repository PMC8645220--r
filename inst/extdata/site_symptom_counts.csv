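site,n_site,attribute,a,b,c,d,freq_pct,printed_ppos,printed_pneg,printed_overall,printed_pabak,printed_kappa,printed_kappa_se,printed_se,printed_se_lo,printed_se_hi,printed_sp,printed_sp_lo,printed_sp_hi,note
Sylhet,278,high_fever,1,7,0,270,0.4,100,99,97,0.95,0.22,0.04,100,3,100,98,95,99,
Sylhet,278,moderate_fever,2,15,4,257,0.7,6,96,93,0.86,0.15,0.05,33,4,78,95,91,97,
Sylhet,278,history_of_fever,37,23,4,214,13,45,94,87,0.80,0.67,0.06,90,77,97,90,86,94,
Sylhet,278,lower_abdominal_pelvic_pain,107,11,81,79,38,19,63,67,0.34,0.37,0.05,57,50,64,88,79,94,
Sylhet,278,abnormal_foul_discharge,11,12,12,243,4.0,13,95,91,0.83,0.43,0.06,48,27,69,95,92,98,
Sylhet,278,fever_only,1,0,0,277,0.4,100,100,100,0.99,0.00,0.00,,,,,,,
Sylhet,278,severe_vaginal_bleeding,4,15,7,252,1.4,7,96,92,0.84,0.23,0.06,36,11,69,94,91,97,
Sylhet,278,severe_headache_blurred_vision,41,22,66,149,15,5,77,68,0.13,0.00,0.00,38,29,48,87,81,92,
Sylhet,278,leaking_urine_stool,0,1,0,277,0.0,,100,100,,0.00,0.00,,,,,,,
Sylhet,278,convulsions_or_unconscious,3,0,0,275,1.1,,100,99,0.96,0.00,0.00,,,,,,,
Sylhet,278,lower_abdominal_pain_no_fever,48,9,76,145,17,,77,69,0.39,0.35,0.05,39,30,48,94,89,97,
Sylhet,278,history_of_fever_only,37,23,4,214,13,45,94,87,0.80,0.67,0.06,90,77,97,90,86,94,
Sylhet,278,abnormal_discharge_no_fever,1,6,7,264,0.4,5,98,95,0.91,0.11,0.06,13,0,53,98,95,99,
Sylhet,278,burning_on_micturition,26,12,41,199,9.4,10,88,81,0.62,0.39,0.06,39,27,52,94,90,97,
Sylhet,278,cough_or_difficulty_breathing,13,14,31,220,4.7,6,91,84,0.68,0.28,0.06,30,17,45,94,90,97,
Sylhet,278,wound_pus_or_pain,8,4,9,257,2.9,31,98,95,0.91,0.53,0.06,47,23,72,99,96,100,
Sylhet,278,breast_swollen_red_painful,4,3,19,252,1.4,12,96,92,0.84,0.24,0.05,17,5,39,99,97,100,
Matiari,300,high_fever,2,2,7,289,0.7,6,98,97,0.94,0.30,0.05,22,3,60,100,98,100,
Matiari,300,moderate_fever,6,11,13,270,2.0,10,96,92,0.84,0.29,0.06,32,13,57,96,93,98,
Matiari,300,history_of_fever,95,31,27,147,32,83,84,81,0.61,0.60,0.06,78,70,85,83,76,88,
Matiari,300,lower_abdominal_pelvic_pain,81,78,27,114,27,64,68,65,0.30,0.31,0.05,75,66,83,59,52,66,
Matiari,300,abnormal_foul_discharge,32,43,23,202,11,100,86,78,0.56,0.36,0.06,58,44,71,82,77,87,
Matiari,300,fever_only,1,0,0,299,0.3,,,100,,0.00,0.06,,,,,,,
Matiari,300,severe_vaginal_bleeding,3,35,3,259,1.0,60,93,87,0.75,0.11,0.04,50,12,88,88,84,92,
Matiari,300,severe_headache_blurred_vision,105,50,43,102,35,76,69,69,0.38,0.38,0.06,71,63,78,67,59,75,
Matiari,300,leaking_urine_stool,2,0,0,298,0.7,,,99,,0.00,,,,,,,,
Matiari,300,convulsions_or_unconscious,0,1,3,296,0.0,,,99,,-0.01,0.05,0,0,71,100,98,100,
Matiari,300,lower_abdominal_pain_no_fever,22,42,23,213,7.3,54,87,78,0.57,0.28,0.06,49,34,64,84,78,88,
Matiari,300,history_of_fever_only,95,31,27,147,32,76,84,78,0.57,0.55,0.06,78,70,85,83,76,88,
Matiari,300,abnormal_discharge_no_fever,5,21,17,257,1.7,34,93,87,0.75,0.14,0.06,23,8,45,92,89,95,
Matiari,300,burning_on_micturition,16,23,11,250,5.3,41,94,89,0.77,0.42,0.06,59,39,78,92,88,95,
Matiari,300,cough_or_difficulty_breathing,37,34,25,204,12,100,87,80,0.61,0.43,0.06,60,46,72,86,81,90,
Matiari,300,wound_pus_or_pain,13,8,11,268,4.3,30,97,94,0.87,0.54,0.06,54,33,74,97,94,99,
Matiari,300,breast_swollen_red_painful,7,37,9,247,2.3,22,91,85,0.69,0.17,0.05,44,20,70,87,83,91,
Karachi,300,high_fever,2,0,0,298,0.7,100,100,99,0.97,0.00,,,,,,,,
Karachi,300,moderate_fever,2,1,4,293,0.7,44,99,98,0.97,0.44,0.05,33,4,78,100,98,100,
Karachi,300,history_of_fever,87,17,39,157,29,76,85,81,0.63,0.61,0.06,69,60,77,90,85,94,
Karachi,300,lower_abdominal_pelvic_pain,113,49,52,86,38,69,63,66,0.33,0.32,0.06,69,61,76,64,55,72,
Karachi,300,abnormal_foul_discharge,19,15,30,236,6.3,46,91,85,0.70,0.37,0.06,39,25,54,94,90,97,
Karachi,300,fever_only,0,0,0,300,0.0,,,,,,,,,,,,,
Karachi,300,severe_vaginal_bleeding,2,9,14,275,0.7,15,96,92,0.85,0.11,0.06,13,2,38,97,94,99,
Karachi,300,severe_headache_blurred_vision,42,84,17,157,14,45,76,66,0.32,0.25,0.05,71,58,82,65,59,71,
Karachi,300,leaking_urine_stool,2,0,0,298,0.7,100,100,99,0.97,0.00,0.00,,,,,,,
Karachi,300,convulsions_or_unconscious,1,4,0,295,0.3,33,99,99,0.97,0.33,0.04,100,3,100,99,97,100,
Karachi,300,lower_abdominal_pain_no_fever,36,42,33,189,12,49,83,75,0.50,0.33,0.06,52,40,64,82,76,87,
Karachi,300,history_of_fever_only,87,17,39,157,29,76,85,81,0.63,0.61,0.06,69,60,77,90,85,94,
Karachi,300,abnormal_discharge_no_fever,3,9,14,274,1.0,21,96,92,0.85,0.17,0.06,18,4,43,97,94,99,
Karachi,300,burning_on_micturition,32,17,31,220,11,57,90,84,0.68,0.48,0.06,51,38,64,93,89,96,
Karachi,300,cough_or_difficulty_breathing,26,28,21,225,0.7,8,90,84,0.80,0.42,0.06,55,40,70,89,84,93,tp_corrected_from_printed_2_to_sum_to_300
Karachi,300,wound_pus_or_pain,25,10,32,233,8.3,54,92,86,0.72,0.47,0.06,44,31,58,96,93,98,
Karachi,300,breast_swollen_red_painful,33,19,40,208,11,53,88,80,0.61,0.41,0.06,45,34,57,92,87,95,
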