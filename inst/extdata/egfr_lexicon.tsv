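# EGFR tokenization lexicon: surface form <TAB> token symbol.
# Surface forms are matched longest-first on normalized (lowercase,
# whitespace-collapsed) text; category is inferred from the symbol suffix.
# -- assay locations --
exon 19	exon_19_location
exon19	exon_19_location
exon 20	exon_20_location
exon20	exon_20_location
t790m	t790m_location
l858r	l858r_location
l861q	l861q_location
g719x	g719x_location
g719s	g719x_location
g719a	g719x_location
g719c	g719x_location
g719s/g719a/g719c	g719x_location
s768i	s768i_location
s78i	s768i_location
# -- test results --
identified	identified_result
positive	identified_result
detected	identified_result
not detected	not_detected_result
not identified	not_detected_result
negative	not_detected_result
no mutation detected	not_detected_result
no mutations detected	not_detected_result
# -- specific results --
deletion	deletion_specific_result
deletions	deletion_specific_result
del	deletion_specific_result
insertion	insertion_specific_result
insertions	insertion_specific_result
ins	insertion_specific_result
# -- conjunctions --
and	conjunction
,	conjunction
# -- test status --
insufficient dna	insufficient_dna_status
test cancelled	cancelled_status
test cancelled due to insufficient dna	cancelled_status
cancelled	cancelled_status
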