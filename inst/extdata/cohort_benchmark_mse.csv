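cohort,diagnosis,mse_linreg,mse_bilstm,mse_lstm,mse_wtlstm,mse_apache_iv_24h,mse_wtlstm_3h,mse_wtlstm_6h,mse_wtlstm_12h
HF,congestive heart failure,17.61,14.75,13.84,13.24,12.80,15.23,15.20,15.05
CVA,cerebrovascular accident or stroke,15.16,12.33,11.59,11.45,11.58,12.72,12.71,12.67
MI,acute myocardial infarction,8.15,6.03,5.54,5.53,6.85,6.10,6.06,6.03
SP,"sepsis, pulmonary",38.77,29.41,24.29,24.31,34.67,29.92,29.76,29.69
SR,"sepsis, renal/UTI",15.24,9.99,9.08,8.84,11.14,10.36,10.32,10.26
RD,rhythm disturbance,10.69,7.71,6.66,6.02,7.54,7.96,7.91,7.72
DK,diabetic ketoacidosis,4.08,2.38,2.39,2.37,2.72,2.44,2.44,2.39
CA,cardiac arrest,38.77,22,20.04,19.22,30.43,24.77,24.37,23.48
CABG,coronary artery bypass grafting,14.08,11.95,9.47,8.78,11.84,12.21,12.07,11.64
EB,emphysema or bronchitis,19.1,12.3,11.58,11.25,13.52,13.06,12.86,12.72
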