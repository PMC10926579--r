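# Core grammar of EGFR result sentences, without the insufficient-DNA /
# test-cancelled status productions. Sentences of those forms are rejected,
# reproducing the failure mode the status extensions were added to close.
S -> Location Result | Location Conjunction S | S Conjunction Location
S -> 'not_detected_result'
Location -> Location Specific_Result | Specific_Result Location
Location -> 'exon_19_location' | 'exon_20_location' | 't790m_location'
Location -> 'l858r_location' | 'l861q_location' | 'g719x_location' | 's768i_location'
Conjunction -> 'conjunction'
Result -> 'identified_result' | 'not_detected_result'
Specific_Result -> 'deletion_specific_result' | 'insertion_specific_result' | EPSILON
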