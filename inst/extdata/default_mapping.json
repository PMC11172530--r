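{
  "name": "default-extraction-mapping",
  "version": "1.0.0",
  "comment": "Parameter -> resource-kind/code rules for the 16 decision-relevant clinical parameters. The source study's own FHIR query catalogue is not public; this mapping is a reconstruction by parameter name. Edit this file, not the code, to adapt the clinical content.",
  "parameters": [
    {"parameter": "age_at_primary_diagnosis", "resource_kind": "observation",
     "code": "age-at-primary-diagnosis", "value_type": "quantity", "unit": "years"},
    {"parameter": "sex", "resource_kind": "patient-demographics",
     "code": "demographics", "value_type": "code"},
    {"parameter": "date_of_first_diagnosis", "resource_kind": "condition",
     "code": "melanoma-first-diagnosis", "value_type": "date"},
    {"parameter": "tumor_thickness_breslow", "resource_kind": "observation",
     "code": "breslow-thickness", "value_type": "quantity", "unit": "mm"},
    {"parameter": "ulceration_status", "resource_kind": "observation",
     "code": "ulceration-status", "value_type": "code"},
    {"parameter": "resection_status", "resource_kind": "procedure",
     "code": "resection-status", "value_type": "code"},
    {"parameter": "mitotic_rate", "resource_kind": "observation",
     "code": "mitotic-rate", "value_type": "quantity", "unit": "1/mm2"},
    {"parameter": "melanoma_setting", "resource_kind": "episode-of-care",
     "code": "melanoma-setting", "value_type": "code"},
    {"parameter": "pT", "resource_kind": "observation",
     "code": "pt-category", "value_type": "code"},
    {"parameter": "lymph_node_sonography", "resource_kind": "diagnostic-report",
     "code": "lymph-node-sonography", "value_type": "code"},
    {"parameter": "metastasis_detection_clinical", "resource_kind": "observation",
     "code": "metastasis-detection-clinical", "value_type": "code"},
    {"parameter": "metastasis_detection_radiological", "resource_kind": "diagnostic-report",
     "code": "metastasis-detection-radiological", "value_type": "code"},
    {"parameter": "tumor_stage", "resource_kind": "condition",
     "code": "ajcc-tumor-stage", "value_type": "code"},
    {"parameter": "braf_status", "resource_kind": "observation",
     "code": "braf-status", "value_type": "code"},
    {"parameter": "slne_status", "resource_kind": "procedure",
     "code": "slne-status", "value_type": "code"},
    {"parameter": "capsular_breakthrough", "resource_kind": "observation",
     "code": "capsular-breakthrough", "value_type": "code"}
  ]
}
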