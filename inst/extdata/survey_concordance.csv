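dp,option,option_text,simulation_selected,count,respondents
DP1a,mup-connection-staging,"The present patient is an MUP patient: connection to the skin tumor center, then staging",FALSE,0,10
DP1a,slne-consultation,"Indication for SLNE consultation, preceded by a lymph node ultrasound examination to rule out a locoregional lymph node metastasis",FALSE,1,10
DP1a,private-practice-referral,Referral to a dermatologist in private practice,FALSE,0,10
DP1a,non-resectable-metastatic,Non-resectable/metastatic setting,FALSE,0,10
DP1a,cannot-determine,"Due to a lack of data, the next treatment step cannot (yet) be determined",TRUE,9,10
DP1b,mup-connection-staging,"The present patient is an MUP patient: connection to the skin tumor center, then staging",FALSE,0,9
DP1b,slne-consultation,"Indication for SLNE consultation, preceded by a lymph node ultrasound examination to rule out a locoregional lymph node metastasis",TRUE,9,9
DP1b,private-practice-referral,Referral to a dermatologist in private practice,FALSE,0,9
DP1b,non-resectable-metastatic,Non-resectable/metastatic setting,FALSE,0,9
DP1b,cannot-determine,"Because of a lack of data, the next treatment step cannot (yet) be determined",FALSE,0,9
DP8,guideline-excision-followup,Guideline-based excision with safety margin plus follow-up care,FALSE,0,9
DP8,slne-with-safety-margin,"Check lymph node sonography examination and tumor markers; then, perform SLNE with guideline-based safety margin",TRUE,9,9
DP16,adjuvant-therapy,Adjuvant therapy,TRUE,9,9
DP16,study-inclusion,Study inclusion options,TRUE,8,9
DP16,guideline-compliant-followup,Guideline-compliant follow-up,TRUE,4,9
DP16,interferon,Interferon,FALSE,0,9
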