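patient_id,ordinal,step_kind,node_id,branch_label,parameter_name,parameter_value,availability
GOLD01,1,task,start,,,,
GOLD01,2,gateway,DP1,,,,
GOLD01,3,parameters-used,DP1,,pT,T3a,present
GOLD01,4,parameters-used,DP1,,melanoma_setting,primary,present
GOLD01,5,parameters-used,DP1,,tumor_thickness_breslow,2.5,present
GOLD01,6,parameters-used,DP1,,ulceration_status,yes,present
GOLD01,7,parameters-used,DP1,,resection_status,R0,present
GOLD01,8,parameters-used,DP1,,age_at_primary_diagnosis,55,present
GOLD01,9,parameters-used,DP1,,date_of_first_diagnosis,2021-03-15,present
GOLD01,10,outgoing-sequence,DP1,slne-consultation,,,
GOLD01,11,gateway,DP2,,,,
GOLD01,12,parameters-used,DP2,,ulceration_status,yes,present
GOLD01,13,parameters-used,DP2,,tumor_thickness_breslow,2.5,present
GOLD01,14,outgoing-sequence,DP2,yes,,,
GOLD01,15,gateway,DP3,,,,
GOLD01,16,parameters-used,DP3,,resection_status,R0,present
GOLD01,17,outgoing-sequence,DP3,r0,,,
GOLD01,18,task,task_safety_margin_excision,,,,
GOLD01,19,gateway,DP4,,,,
GOLD01,20,parameters-used,DP4,,resection_status,R0,present
GOLD01,21,outgoing-sequence,DP4,r0,,,
GOLD01,22,gateway,DP5,,,,
GOLD01,23,parameters-used,DP5,,melanoma_setting,primary,present
GOLD01,24,outgoing-sequence,DP5,no,,,
GOLD01,25,gateway,DP7,,,,
GOLD01,26,parameters-used,DP7,,tumor_thickness_breslow,2.5,present
GOLD01,27,outgoing-sequence,DP7,gt-0.75,,,
GOLD01,28,gateway,DP8,,,,
GOLD01,29,parameters-used,DP8,,tumor_thickness_breslow,2.5,present
GOLD01,30,parameters-used,DP8,,ulceration_status,yes,present
GOLD01,31,parameters-used,DP8,,mitotic_rate,2,present
GOLD01,32,outgoing-sequence,DP8,slne-indicated,,,
GOLD01,33,task,task_tumor_markers_check,,,,
GOLD01,34,gateway,DP9,,,,
GOLD01,35,parameters-used,DP9,,lymph_node_sonography,remarkable,present
GOLD01,36,outgoing-sequence,DP9,remarkable,,,
GOLD01,37,gateway,DP12,,,,
GOLD01,38,parameters-used,DP12,,metastasis_detection_clinical,no,present
GOLD01,39,parameters-used,DP12,,metastasis_detection_radiological,no,present
GOLD01,40,outgoing-sequence,DP12,no,,,
GOLD01,41,gateway,DP13,,,,
GOLD01,42,parameters-used,DP13,,tumor_stage,IIIB,present
GOLD01,43,outgoing-sequence,DP13,yes,,,
GOLD01,44,gateway,DP14,,,,
GOLD01,45,parameters-used,DP14,,slne_status,positive,present
GOLD01,46,outgoing-sequence,DP14,positive,,,
GOLD01,47,gateway,DP15,,,,
GOLD01,48,parameters-used,DP15,,slne_status,positive,present
GOLD01,49,parameters-used,DP15,,capsular_breakthrough,no,present
GOLD01,50,outgoing-sequence,DP15,no,,,
GOLD01,51,task,chk_individualized,,,,
GOLD01,52,gateway,DP16,,,,
GOLD01,53,parameters-used,DP16,,tumor_stage,IIIB,present
GOLD01,54,parameters-used,DP16,,braf_status,mutation,present
GOLD01,55,parameters-used,DP16,,slne_status,positive,present
GOLD01,56,parameters-used,DP16,,capsular_breakthrough,no,present
GOLD01,57,outgoing-sequence,DP16,adjuvant-therapy,,,
GOLD01,58,task,task_adjuvant_option,,,,
GOLD01,59,outgoing-sequence,DP16,study-inclusion,,,
GOLD01,60,task,task_study_screening,,,,
GOLD01,61,outgoing-sequence,DP16,guideline-compliant-followup,,,
GOLD01,62,task,task_followup_plan,,,,
GOLD01,63,task,join_dp16,,,,
GOLD01,64,gateway,DP17,,,,
GOLD01,65,parameters-used,DP17,,tumor_stage,IIIB,present
GOLD01,66,outgoing-sequence,DP17,indicated,,,
GOLD01,67,gateway,DP18,,,,
GOLD01,68,parameters-used,DP18,,braf_status,mutation,present
GOLD01,69,outgoing-sequence,DP18,targeted-therapy,,,
GOLD01,70,task,task_staging_imaging,,,,
GOLD01,71,gateway,DP10.2,,,,
GOLD01,72,outgoing-sequence,DP10.2,yes,,,
GOLD01,73,gateway,DP19,,,,
GOLD01,74,parameters-used,DP19,,braf_status,mutation,present
GOLD01,75,outgoing-sequence,DP19,no,,,
GOLD01,76,gateway,DP20,,,,
GOLD01,77,parameters-used,DP20,,braf_status,mutation,present
GOLD01,78,outgoing-sequence,DP20,targeted,,,
GOLD01,79,gateway,DP21,,,,
GOLD01,80,parameters-used,DP21,,braf_status,mutation,present
GOLD01,81,outgoing-sequence,DP21,dabrafenib-trametinib,,,
GOLD01,82,task,task_adjuvant_admin,,,,
GOLD01,83,task,task_followup_care,,,,
GOLD01,84,gateway,DP23,,,,
GOLD01,85,parameters-used,DP23,,tumor_stage,IIIB,present
GOLD01,86,outgoing-sequence,DP23,stage-iii-or-higher,,,
GOLD01,87,gateway,DP24,,,,
GOLD01,88,parameters-used,DP24,,date_of_first_diagnosis,2021-03-15,present
GOLD01,89,outgoing-sequence,DP24,year-1-3,,,
GOLD01,90,gateway,DP25,,,,
GOLD01,91,parameters-used,DP25,,date_of_first_diagnosis,2021-03-15,present
GOLD01,92,outgoing-sequence,DP25,no,,,
GOLD01,93,gateway,DP27,,,,
GOLD01,94,parameters-used,DP27,,metastasis_detection_clinical,no,present
GOLD01,95,parameters-used,DP27,,metastasis_detection_radiological,no,present
GOLD01,96,outgoing-sequence,DP27,no,,,
GOLD01,97,end-event,end_ongoing_followup,,,,
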