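sample_id	recurrence_status	time_to_recurrence_months	followup_months
SAMPLE_01	yes	14.5	14.5
SAMPLE_02	no		61.0
SAMPLE_03	no		39.0
SAMPLE_04	yes	44.0	44.0
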