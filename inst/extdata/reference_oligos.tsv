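id	notation	reported_mass	comment
1	5'-NH2-C6-TCGAATGACTCCGTATrG-3'-Propargyl	5732	headpiece fragment; reported sequence is one residue shorter than the matching segment of oligo 3 and its reported mass is not reproducible from it
2	5'-azido-TATAGCGCGATATACACACTGGCGAGCTTGCGTACTG	11414	azido tag fragment for single-junction ligation
3	5'-Biotin-PEG4-CONH-C6-TCGAATGACTCCGATATrG^trTATAGCGCGATATACACACTGGCGAGCTTGCGTACTG	17619	single-triazole ligation product; biotin-labelled template
4	5'-Cy5-CAGTACGCAAGCTCG	5095	Cy5 extension primer (15 printed bases)
5	5'-Cy5-CAGTACGCAAGCTCGCCAGTGTGTATATCGCGCTATA	11882	stalled extension product on template 3 (also reported in-text as 11,880)
6	5'-Cy5-CAGTACGCAAGCTCGCCAGTGTGTATATCGCGCTATACATATCGGAGTCATTCGA	17443	full-length extension product on template 3
7	5'-Biotin-PEG4-CONH-C6-TCGAATGACTCCGATATrGTATAGCGCGATATACACACTGGCGAGCTTGCGTACTG	17811	all-phosphodiester control template
8	5'-Biotin-PEG4-CONH-C6-TCGAATGACTCCGATATrG^trTACACACTGGCGAGCTTGCGTACTG	13463	single-triazole template with 8-base run-up
9	5'-Biotin-TEG-spacerC3-spacerC3-TCGAATGACTCCGATATrG^trTATGCGTACAGTCCU^trTATAGCGCGATATACACACTGGCGAGCTTGCGTACTG	22235	double-triazole template (one rG^tr-T, one U^tr-T junction)
10	5'-Biotin-TEG-spacerC3-spacerC3-TCGAATGACTCCGATATrG^trTATGCGTACAGTCCU^trTATGCGTACAGTCCU^trTATAGCGCGATATACACACTGGCGAGCTTGCGTACTG	26848	triple-triazole template (one rG^tr-T, two U^tr-T junctions)
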