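upper_level_class	total	n_faecal_in_vitro	n_antibiotic_reduction	n_germfree_reduction
Amino acids, peptides, and analogues	62	25	36	28
Phenylpropanoids and polyketides	46	44	11	16
Fatty acyls	45	30	25	6
Bile acids, alcohols and derivatives	45	33	11	12
Phenols	31	18	15	15
Indoles and derivatives	23	13	10	12
Carbohydrates and carbohydrate conjugates	22	0	16	9
Organic nitrogen compounds	22	15	10	10
Benzoic acids and derivatives	21	16	7	7
Carboxylic acids and derivatives	14	11	7	9
Benzene and substituted derivatives	12	10	3	4
Hydroxy acids and derivatives	10	4	5	2
Steroids and steroid derivatives	10	9	2	1
Alcohols and polyols	9	6	2	1
Nucleosides, nucleotides, and analogues	9	0	5	5
Organic acids and derivatives	8	1	6	4
Pyridines and derivatives	7	0	4	5
Prenol lipids	7	0	3	4
Keto acids and derivatives	7	1	5	4
Purines and purine derivatives	7	1	4	6
Carbonyl compounds	6	4	2	0
Lipids and lipid-like molecules	6	1	5	0
Tetrapyrroles and derivatives	5	4	4	1
Pyrimidines and pyrimidine derivatives	5	1	4	2
Organoheterocyclic compounds	4	3	1	1
Imidazoles	4	0	2	3
Pteridines and derivatives	3	2	2	1
Lignans, neolignans and related compounds	2	2	0	1
Alkaloids and derivatives	1	1	1	0
Organosulfur compounds	1	0	0	1
Hybrid peptides	1	0	1	0
Phenol ethers	1	1	0	0
Phenol esters	1	1	0	0
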