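"nodule_id","patient_id","composition","echogenicity","shape","margins","echogenic_foci","vascular_pattern","major_diameter_mm","favoring_fna","against_fna","exclusions","family_history_thyroid_cancer","personal_history_thyroid_cancer","pathologic_adenopathy","tsh_mUI_per_L","calcitonin_pg_per_mL","tpo_ab_elevated","on_levothyroxine","cytology","diagnosis_label","malignant","histologic_diameter_mm"
"N0001","P001","solid","very_hypoechoic","oval_or_round","smooth_or_regular","none","peripheral_or_low",4.9,"","limited_life_expectancy_or_comorbidity;pregnancy","",FALSE,FALSE,FALSE,1.93,,FALSE,FALSE,"TIR2","goiter",FALSE,3.2
"N0002","P001","solid","isoechoic","taller_than_wide","spiculated_sharp_angles","microcalcification","peripheral_or_low",18.1,"","limited_life_expectancy_or_comorbidity;pregnancy","",FALSE,FALSE,FALSE,1.93,,FALSE,FALSE,"TIR5","papillary_cancer",TRUE,15
"N0003","P002","solid","very_hypoechoic","taller_than_wide","smooth_or_regular","none","intranodular",15,"","","",FALSE,FALSE,FALSE,2.27,,FALSE,FALSE,"TIR3A","papillary_cancer",TRUE,
"N0004","P004","solid","isoechoic","oval_or_round","smooth_or_regular","none","intranodular",8.8,"","","",FALSE,FALSE,FALSE,1.6,,TRUE,FALSE,"TIR3B","adenoma",FALSE,5.3
"N0005","P003","solid","isoechoic","oval_or_round","smooth_or_regular","none","peripheral_or_low",8.5,"","","",TRUE,FALSE,FALSE,1.18,,TRUE,FALSE,"TIR1","goiter",FALSE,8.3
"N0006","P001","solid","hypoechoic","oval_or_round","smooth_or_regular","difficult_to_characterize","peripheral_or_low",10.8,"","limited_life_expectancy_or_comorbidity;pregnancy","",FALSE,FALSE,FALSE,1.93,,FALSE,FALSE,"TIR4","papillary_cancer",TRUE,12.6
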