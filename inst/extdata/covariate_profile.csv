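variable,group,type,n,count,mean,sd
age,IHD,numeric,91,NA,64.73,10.15
age,MA,numeric,29,NA,64.55,10.02
age,control,numeric,66,NA,62.77,8.21
male_sex,IHD,binary,91,64,NA,NA
male_sex,MA,binary,29,19,NA,NA
male_sex,control,binary,66,37,NA,NA
diabetes,IHD,binary,91,39,NA,NA
diabetes,MA,binary,29,15,NA,NA
diabetes,control,binary,66,30,NA,NA
smoker,IHD,binary,91,44,NA,NA
smoker,MA,binary,29,14,NA,NA
smoker,control,binary,66,30,NA,NA
hypertension,IHD,binary,91,62,NA,NA
hypertension,MA,binary,29,19,NA,NA
hypertension,control,binary,66,36,NA,NA
dyslipidemia,IHD,binary,91,27,NA,NA
dyslipidemia,MA,binary,29,10,NA,NA
dyslipidemia,control,binary,66,17,NA,NA
bmi,IHD,numeric,91,NA,23.98,3.17
bmi,MA,numeric,29,NA,25.06,2.82
bmi,control,numeric,66,NA,23.63,3.91
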