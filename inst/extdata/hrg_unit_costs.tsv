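category	hrg_code	unit	unit_cost	price_year	source_note
lf_procedure	HN43B	procedure	2936	2019	HRG reference cost, limited fasciectomy episode
wound_clinic	HN46Z	attendance	196	2019	HRG reference cost, wound clinic attendance
injection_visit	HN45A	episode	1143	2019	HRG reference cost, collagenase injection episode (drug included)
manipulation_visit	HN46Z	attendance	196	2019	HRG reference cost, manipulation attendance
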