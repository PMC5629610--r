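ive	ion
ic	ia
ia	ic
al	um
um	al
osis	otic
otic	osis
emia	emic
emic	emia
oma	omatous
omatous	oma
y	ic
ical	y
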