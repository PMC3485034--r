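"survey_id","title","type","collection_year","percent_cards_seen","confirmation_method","cohort_min_months","cohort_max_months","sample_size"
"egy_dhs","Egypt DHS","DHS",2006,85,"either",12,23,5000
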