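locus	sativa	meridionalis	punctata	brachyantha
d1	present	present	absent	absent
d2	present	present	absent	absent
d3	present	present	absent	absent
d4	present	present	absent	absent
d5	present	present	absent	absent
d6	present	present	present	absent
d7	present	present	absent	absent
d8	present	present	absent	absent
d9	present	present	absent	absent
d10	present	present	absent	absent
d11	present	present	absent	absent
d12	present	present	present	absent
d13	present	present	absent	absent
d14	present	present	absent	absent
d15	present	unclear	unclear	absent
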