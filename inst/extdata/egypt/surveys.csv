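"survey_id","country","vaccine","cohort_year","coverage","evidence"
"egy_dhs","egy","dtp3",2004,93.5,"either"
"egy_dhs","egy","dtp3",2005,95,"either"
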