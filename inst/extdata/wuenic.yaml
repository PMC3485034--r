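window:
- 1997
- 2011
vaccines:
- bcg
- dtp1
- dtp2
- dtp3
- hepb3
- hib3
- mcv
- mcv1
- mcv2
- pol1
- pol3
- pcv3
- rcv1
- yfv
- rotac
support_threshold: 10.0
min_sample_size: 300
jump_threshold: 20.0
exclude_sustained_jumps: no
cohort_min_months: 12
cohort_max_months: 59
survey_weighting: none
dtp1_poly:
  a: -0.0066
  b: 0.4799
  c: 16.67
calibration: multiplicative
source_precedence:
- reported
- gov
- admin
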