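# Example chain building-block library (fatty acids and fatty alcohols).
# positions: delta-nomenclature locants from the carboxyl/hydroxyl carbon,
# semicolon-separated, e.g. "5Z;8Z;11Z;14Z".
kind	carbons	double_bonds	positions	trivial_name
fatty-acid	14	0		myristic acid
fatty-acid	16	0		palmitic acid
fatty-acid	16	1	9Z	palmitoleic acid
fatty-acid	18	0		stearic acid
fatty-acid	18	1	9Z	oleic acid
fatty-acid	18	2	9Z;12Z	linoleic acid
fatty-acid	18	3	9Z;12Z;15Z	alpha-linolenic acid
fatty-acid	20	4	5Z;8Z;11Z;14Z	arachidonic acid
fatty-acid	20	5	5Z;8Z;11Z;14Z;17Z	eicosapentaenoic acid
fatty-acid	22	6	4Z;7Z;10Z;13Z;16Z;19Z	docosahexaenoic acid
fatty-alcohol	16	0		hexadecanol
fatty-alcohol	18	0		octadecanol
fatty-alcohol	18	1	9Z	oleyl alcohol
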