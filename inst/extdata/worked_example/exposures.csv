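period_id,unit_domain,denominator_type,exposure_count,scaling_constant
2025-Q1,hospital_wide,patient_days,50000,1000
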