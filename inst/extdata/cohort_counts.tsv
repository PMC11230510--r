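cohort	n_patients	n_kataegis_positive	n_events	n_clonal_events	n_hr_events	n_hr_events_within_1kb
studied	188	65	249	174	182	89
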