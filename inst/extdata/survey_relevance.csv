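dp,parameter,display_name,algorithm_usage,relevance_pct,respondents
DP1a,age_at_primary_diagnosis,Patient age (at primary diagnosis),explicit,70.0,10
DP1a,sex,Sex,unused,10.0,10
DP1a,date_of_first_diagnosis,Date of first diagnosis,explicit,70.0,10
DP1a,ulceration_status,Ulceration status,explicit,80.0,10
DP1a,resection_status,Resection status,explicit,80.0,10
DP1a,additional_lymph_node_sonography,Lymph node sonography findings,additional,NA,10
DP1a,additional_lymph_node_status,Lymph node status,additional,NA,10
DP1a,additional_mitotic_rate,Mitotic rate,additional,NA,10
DP1a,additional_apparative_staging,(Apparative) Staging,additional,NA,10
DP1a,additional_tumor_stage,Tumor stage,additional,NA,10
DP1a,additional_tumor_thickness,Tumor thickness,additional,90.0,10
DP1b,age_at_primary_diagnosis,Patient age (at primary diagnosis),explicit,66.7,9
DP1b,sex,Sex,unused,11.1,9
DP1b,date_of_first_diagnosis,Date of first diagnosis,explicit,77.8,9
DP1b,tumor_thickness_breslow,Current tumor thickness,explicit,100.0,9
DP1b,ulceration_status,Ulceration status,explicit,66.7,9
DP1b,resection_status,Resection status,explicit,88.9,9
DP1b,additional_general_condition,General condition/morbidity,additional,NA,9
DP1b,additional_localization_primary,Localization of primary tumor,additional,NA,9
DP1b,additional_lymph_node_sonography,Lymph node sonography findings,additional,NA,9
DP1b,additional_mitotic_rate,Mitotic rate,additional,NA,9
DP8,age_at_primary_diagnosis,Patient age (at primary diagnosis),explicit,66.7,9
DP8,sex,Sex,unused,22.2,9
DP8,date_of_first_diagnosis,Date of first diagnosis,explicit,77.8,9
DP8,tumor_thickness_breslow,Current tumor thickness,explicit,88.9,9
DP8,ulceration_status,Ulceration status,explicit,66.7,9
DP8,mitotic_rate,Mitotic rate,unused,55.6,9
DP8,melanoma_setting,Current melanoma setting,unused,55.6,9
DP8,pT,pT,explicit,77.8,9
DP8,lymph_node_sonography,Lymph node sonography findings,explicit,100.0,9
DP8,metastasis_detection_clinical,Metastasis detection,explicit,88.9,9
DP8,resection_status,Resection status,unused,88.9,9
DP8,additional_tumor_markers,"Tumor markers (S100, LDH)",additional,NA,9
DP16,age_at_primary_diagnosis,Patient age (at primary diagnosis),unused,77.8,9
DP16,sex,Sex,unused,22.2,9
DP16,date_of_first_diagnosis,Date of first diagnosis,unused,77.8,9
DP16,tumor_thickness_breslow,Current tumor thickness,implicit,77.8,9
DP16,ulceration_status,Ulceration status,implicit,77.8,9
DP16,mitotic_rate,Mitotic rate,unused,44.4,9
DP16,melanoma_setting,Current melanoma setting,unused,44.4,9
DP16,pT,pT,implicit,66.7,9
DP16,lymph_node_sonography,Lymph node sonography findings,implicit,88.9,9
DP16,metastasis_detection_clinical,Metastasis detection (clinical),implicit,88.9,9
DP16,tumor_stage,Tumor stage,explicit,88.9,9
DP16,resection_status,Resection status,implicit,77.8,9
DP16,braf_status,BRAF status,explicit,100.0,9
DP16,metastasis_detection_radiological,Metastasis detection (radiological),implicit,77.8,9
DP16,slne_status,SLNE status,explicit,88.9,9
DP16,capsular_breakthrough,Capsular breakthrough,explicit,88.9,9
DP16,additional_staging,Staging,additional,NA,9
DP16,additional_tumor_markers,"Tumor markers (S100, LDH)",additional,NA,9
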