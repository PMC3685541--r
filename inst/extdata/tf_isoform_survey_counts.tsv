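key	label	n
total_considered	Total considered	938
no_evidence_for_alternative_transcripts	No evidence for alternative transcripts	677
alternative_transcripts_encode_same_protein	Alternative transcripts encode same protein	64
annotated_distinct_isoforms	Alternative transcripts annotated to encode different isoforms	197
unique_starting_exon_strong	Alternative unique starting exon - strong evidence	21
unique_starting_exon_weak	Alternative unique starting exon - weak evidence	7
nested_alternative_starts	Nested alternative starts	22
alternative_terminal_exon_strong	Alternative terminal exon - strong evidence	0
alternative_terminal_exon_weak	Alternative terminal exon - weak evidence	23
internal_exon_strong	Non-constitutive internal exon - strong evidence	0
internal_exon_weak	Non-constitutive internal exon - weak evidence	5
internal_intron_strong	Non-constitutive internal intron - strong evidence	3
internal_intron_weak	Non-constitutive internal intron - weak evidence	3
splice_site_selection_strong	Alternative splice site selection - strong evidence	4
splice_site_selection_weak	Alternative splice site selection - weak evidence	20
multiple_mechanisms_strong	Alternative transcripts by multiple mechanisms - strong evidence	9
multiple_mechanisms_weak	Alternative transcripts by multiple mechanisms - weak evidence	25
evidence_considered_invalid	Alternative transcript evidence considered invalid	55
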