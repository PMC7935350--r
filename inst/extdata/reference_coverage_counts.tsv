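source	covered_by_count	source_total	cover_to_count	target_total
ISOSeq0215	45612	56399	21498	49758
ISOSeq0215hq	8826	9352	9178	49758
CJ_FLcDNA	15903	23111	16814	49758
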