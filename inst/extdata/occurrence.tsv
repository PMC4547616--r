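# Example lipid occurrence annotations (synthetic records for demonstration):
# lipid id, GO/Uberon term, NCBI taxon, ECO evidence code, optional PMID/source text
lipid_id	term_id	taxon_id	eco	pmid	source_text
LPD8CBDD04DAEEB58A2	UBERON:0002107	9606	ECO:0000269	24243886	observed in liver extracts
LPD8CBDD04DAEEB58A2	GO:0005886	10090	ECO:0000305		
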