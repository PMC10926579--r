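# Grammar of EGFR result sentences (default, with status extensions).
# The first rule's left-hand side is the start symbol; rule order fixes the
# canonical-derivation tie-break.
S -> Location Result | Location Conjunction S | S Conjunction Location
S -> 'not_detected_result'
S -> InsufficientDNA
S -> Cancelled
Location -> Location Specific_Result | Specific_Result Location
Location -> 'exon_19_location' | 'exon_20_location' | 't790m_location'
Location -> 'l858r_location' | 'l861q_location' | 'g719x_location' | 's768i_location'
Conjunction -> 'conjunction'
Result -> 'identified_result' | 'not_detected_result'
Specific_Result -> 'deletion_specific_result' | 'insertion_specific_result' | EPSILON
InsufficientDNA -> 'insufficient_dna_status'
Cancelled -> 'cancelled_status'
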