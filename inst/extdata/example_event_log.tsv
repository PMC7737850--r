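patient_id	event_code	count
p001	E00..	2
p001	bd3..	1
p002	E00..	1
p002	F110.	3
p003	bd3..	2
p003	E00..	1
p003	F110.	1
p004	G20..	4
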