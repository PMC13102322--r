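event_id,event_date,event_type,reached_patient,detection_mode,unit_domain,severity_class
nm-01,2025-01-06,near_miss,no,human,pharmacy,minor
nm-02,2025-01-13,near_miss,no,alarm,icu,minor
nm-03,2025-01-20,near_miss,no,human,ward,minor
nm-04,2025-01-27,near_miss,no,patient,laboratory,minor
nm-05,2025-02-03,near_miss,no,chance,emergency_department,minor
nm-06,2025-02-10,near_miss,no,human,pharmacy,moderate
nm-07,2025-02-17,near_miss,no,alarm,icu,moderate
nm-08,2025-02-24,near_miss,no,human,ward,moderate
nm-09,2025-03-03,near_miss,no,patient,laboratory,major
nm-10,2025-03-10,near_miss,no,chance,emergency_department,catastrophic
hi-01,2025-01-02,harmful_incident,yes,human,ward,
hi-02,2025-02-11,harmful_incident,yes,human,icu,
hi-03,2025-02-12,harmful_incident,yes,alarm,operating_room,
hi-04,2025-02-13,harmful_incident,yes,patient,pharmacy,
hi-05,2025-02-14,harmful_incident,yes,human,emergency_department,
hi-06,2025-02-15,harmful_incident,yes,human,ward,
hi-07,2025-02-16,harmful_incident,yes,human,icu,
hi-08,2025-02-17,harmful_incident,yes,alarm,operating_room,
hi-09,2025-02-18,harmful_incident,yes,patient,pharmacy,
hi-10,2025-02-19,harmful_incident,yes,human,emergency_department,
hi-11,2025-02-20,harmful_incident,yes,human,ward,
hi-12,2025-02-21,harmful_incident,yes,human,icu,
hi-13,2025-02-22,harmful_incident,yes,alarm,operating_room,
hi-14,2025-02-23,harmful_incident,yes,patient,pharmacy,
hi-15,2025-02-24,harmful_incident,yes,human,emergency_department,
hi-16,2025-02-25,harmful_incident,yes,human,ward,
hi-17,2025-02-26,harmful_incident,yes,human,icu,
hi-18,2025-02-27,harmful_incident,yes,alarm,operating_room,
hi-19,2025-02-28,harmful_incident,yes,patient,pharmacy,
hi-20,2025-03-01,harmful_incident,yes,human,emergency_department,
hi-21,2025-03-02,harmful_incident,yes,human,ward,
hi-22,2025-03-03,harmful_incident,yes,human,icu,
hi-23,2025-03-04,harmful_incident,yes,alarm,operating_room,
hi-24,2025-03-05,harmful_incident,yes,patient,pharmacy,
hi-25,2025-03-06,harmful_incident,yes,human,emergency_department,
hi-26,2025-03-07,harmful_incident,yes,human,ward,
hi-27,2025-03-08,harmful_incident,yes,human,icu,
hi-28,2025-03-09,harmful_incident,yes,alarm,operating_room,
hi-29,2025-03-10,harmful_incident,yes,patient,pharmacy,
hi-30,2025-03-11,harmful_incident,yes,human,emergency_department,
hi-31,2025-03-12,harmful_incident,yes,human,ward,
hi-32,2025-03-13,harmful_incident,yes,human,icu,
hi-33,2025-03-14,harmful_incident,yes,alarm,operating_room,
hi-34,2025-03-15,harmful_incident,yes,patient,pharmacy,
hi-35,2025-03-16,harmful_incident,yes,human,emergency_department,
hi-36,2025-03-17,harmful_incident,yes,human,ward,
hi-37,2025-03-18,harmful_incident,yes,human,icu,
hi-38,2025-03-19,harmful_incident,yes,alarm,operating_room,
hi-39,2025-03-20,harmful_incident,yes,patient,pharmacy,
hi-40,2025-03-21,harmful_incident,yes,human,emergency_department,
hi-41,2025-03-22,harmful_incident,yes,human,ward,
hi-42,2025-03-23,harmful_incident,yes,human,icu,
hi-43,2025-03-24,harmful_incident,yes,alarm,operating_room,
hi-44,2025-03-25,harmful_incident,yes,patient,pharmacy,
hi-45,2025-03-26,harmful_incident,yes,human,emergency_department,
hi-46,2025-03-27,harmful_incident,yes,human,ward,
hi-47,2025-03-28,harmful_incident,yes,human,icu,
hi-48,2025-03-29,harmful_incident,yes,alarm,operating_room,
hi-49,2025-03-30,harmful_incident,yes,patient,pharmacy,
hi-50,2025-03-31,harmful_incident,yes,human,emergency_department,
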