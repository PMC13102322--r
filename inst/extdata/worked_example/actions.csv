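action_id,event_id,report_date,implemented_date,sustainment_verified_date,sustainment_evidence
act-01,nm-01,2025-01-06,2025-02-20,2025-08-25,audit
act-02,nm-02,2025-01-13,2025-03-10,2025-09-10,performance_data
act-03,nm-06,2025-02-10,2025-04-15,,none
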