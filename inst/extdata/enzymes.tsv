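# Example enzyme-reaction links (synthetic records for demonstration):
# UniProtKB accession, Rhea reaction id, ECO evidence code, optional PMID,
# optional participating lipid id
protein_acc	reaction_id	eco	pmid	lipid_id
Q8TCG2	RHEA:36179	ECO:0000269	18094042	
O14939	RHEA:14445	ECO:0000305		LPD8B1377831ABBCD24
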