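equation_id,form,term,covariate,value
eye_bdr,exponential,intercept,,-3.49
eye_bdr,exponential,coef,hba1c,0.25
eye_bdr,exponential,center,hba1c,8.3
eye_pdr,exponential,intercept,,-4.41
eye_pdr,exponential,coef,hba1c,0.30
eye_pdr,exponential,center,hba1c,8.3
eye_me,exponential,intercept,,-4.13
eye_me,exponential,coef,hba1c,0.25
eye_me,exponential,center,hba1c,8.3
eye_svl,exponential,intercept,,-3.08
eye_svl,exponential,coef,hba1c,0.10
eye_svl,exponential,center,hba1c,8.3
le_neuro,exponential,intercept,,-4.82
le_neuro,exponential,coef,hba1c,0.20
le_neuro,exponential,center,hba1c,8.3
le_neuro,exponential,coef,bmi,0.03
le_neuro,exponential,center,bmi,35.9
le_pvd,exponential,intercept,,-4.19
le_pvd,exponential,coef,hba1c,0.12
le_pvd,exponential,center,hba1c,8.3
le_pvd,exponential,coef,smoker,0.50
le_pvd,exponential,center,smoker,0.265
le_amp,exponential,intercept,,-3.90
le_amp,exponential,coef,hba1c,0.25
le_amp,exponential,center,hba1c,8.3
le_amp_pvd,exponential,intercept,,-3.34
le_amp_pvd,exponential,coef,hba1c,0.25
le_amp_pvd,exponential,center,hba1c,8.3
ren_micro,exponential,intercept,,-3.68
ren_micro,exponential,coef,hba1c,0.20
ren_micro,exponential,center,hba1c,8.3
ren_micro,exponential,coef,sbp,0.010
ren_micro,exponential,center,sbp,141.5
ren_macro,exponential,intercept,,-3.10
ren_macro,exponential,coef,hba1c,0.20
ren_macro,exponential,center,hba1c,8.3
ren_macro,exponential,coef,sbp,0.012
ren_macro,exponential,center,sbp,141.5
ren_esrd,exponential,intercept,,-3.34
ren_esrd,exponential,coef,hba1c,0.10
ren_esrd,exponential,center,hba1c,8.3
ren_esrd,exponential,coef,egfr,-0.020
ren_esrd,exponential,center,egfr,77.5
mac_ihd,exponential,intercept,,-4.41
mac_ihd,exponential,coef,hba1c,0.12
mac_ihd,exponential,center,hba1c,8.3
mac_ihd,exponential,coef,sbp,0.006
mac_ihd,exponential,center,sbp,141.5
mac_ihd,exponential,coef,ldl,0.20
mac_ihd,exponential,center,ldl,2.75
mac_ihd,exponential,coef,smoker,0.30
mac_ihd,exponential,center,smoker,0.265
mac_ihd,exponential,coef,age,0.05
mac_ihd,exponential,center,age,61
mac_ihd,exponential,coef,female,-0.40
mac_ihd,exponential,center,female,0.359
mac_mi,weibull,intercept,,-4.87
mac_mi,weibull,shape,,1.20
mac_mi,weibull,coef,hba1c,0.13
mac_mi,weibull,center,hba1c,8.3
mac_mi,weibull,coef,sbp,0.008
mac_mi,weibull,center,sbp,141.5
mac_mi,weibull,coef,ldl,0.25
mac_mi,weibull,center,ldl,2.75
mac_mi,weibull,coef,hdl,-0.60
mac_mi,weibull,center,hdl,1.21
mac_mi,weibull,coef,smoker,0.40
mac_mi,weibull,center,smoker,0.265
mac_mi,weibull,coef,age,0.06
mac_mi,weibull,center,age,61
mac_mi,weibull,coef,female,-0.50
mac_mi,weibull,center,female,0.359
mac_mi_sub,logistic,intercept,,-2.751
mac_mi_sub,logistic,coef,hba1c,0.08
mac_mi_sub,logistic,center,hba1c,8.3
mac_mi_sub,logistic,coef,age,0.04
mac_mi_sub,logistic,center,age,61
mac_stroke,exponential,intercept,,-5.10
mac_stroke,exponential,coef,hba1c,0.10
mac_stroke,exponential,center,hba1c,8.3
mac_stroke,exponential,coef,sbp,0.012
mac_stroke,exponential,center,sbp,141.5
mac_stroke,exponential,coef,smoker,0.35
mac_stroke,exponential,center,smoker,0.265
mac_stroke,exponential,coef,age,0.07
mac_stroke,exponential,center,age,61
mac_stroke,exponential,coef,female,-0.20
mac_stroke,exponential,center,female,0.359
mac_stroke_sub,exponential,intercept,,-2.98
mac_stroke_sub,exponential,coef,hba1c,0.06
mac_stroke_sub,exponential,center,hba1c,8.3
mac_stroke_sub,exponential,coef,age,0.05
mac_stroke_sub,exponential,center,age,61
mac_hf,exponential,intercept,,-5.10
mac_hf,exponential,coef,hba1c,0.10
mac_hf,exponential,center,hba1c,8.3
mac_hf,exponential,coef,bmi,0.04
mac_hf,exponential,center,bmi,35.9
mac_hf,exponential,coef,age,0.07
mac_hf,exponential,center,age,61
mac_hf,exponential,coef,egfr,-0.010
mac_hf,exponential,center,egfr,77.5
mort_other,exponential,intercept,,-4.30
mort_other,exponential,coef,age,0.085
mort_other,exponential,center,age,61
mort_other,exponential,coef,female,-0.25
mort_other,exponential,center,female,0.359
mort_other,exponential,coef,smoker,0.35
mort_other,exponential,center,smoker,0.265
mort_other,exponential,coef,hba1c,0.06
mort_other,exponential,center,hba1c,8.3
mort_other,exponential,coef,hist_mi,0.50
mort_other,exponential,center,hist_mi,0
mort_other,exponential,coef,hist_stroke,0.50
mort_other,exponential,center,hist_stroke,0
mort_other,exponential,coef,hist_hf,0.80
mort_other,exponential,center,hist_hf,0
mort_other,exponential,coef,hist_esrd,1.20
mort_other,exponential,center,hist_esrd,0
mort_other,exponential,coef,hist_amp,0.60
mort_other,exponential,center,hist_amp,0
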