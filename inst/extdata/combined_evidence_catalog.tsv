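metabolite_id	name	upper_level_class	has_faecal_in_vitro	has_in_vivo_reduction
CMB001	Alanine	Amino acids, peptides, and analogues	1	1
CMB002	Asparagine	Amino acids, peptides, and analogues	1	1
CMB003	Aspartic acid	Amino acids, peptides, and analogues	1	1
CMB004	Citrulline	Amino acids, peptides, and analogues	1	1
CMB005	delta-Aminovaleric acid	Amino acids, peptides, and analogues	1	1
CMB006	gamma-Aminobutyric acid	Amino acids, peptides, and analogues	1	1
CMB007	Glutamic acid	Amino acids, peptides, and analogues	1	1
CMB008	Glycine	Amino acids, peptides, and analogues	1	1
CMB009	Histidine	Amino acids, peptides, and analogues	1	1
CMB010	Homoserine	Amino acids, peptides, and analogues	1	1
CMB011	L-alpha-Aminobutyric acid	Amino acids, peptides, and analogues	1	1
CMB012	Leucine	Amino acids, peptides, and analogues	1	1
CMB013	Lysine	Amino acids, peptides, and analogues	1	1
CMB014	Methionine	Amino acids, peptides, and analogues	1	1
CMB015	Ornithine	Amino acids, peptides, and analogues	1	1
CMB016	Phenylalanine	Amino acids, peptides, and analogues	1	1
CMB017	Proline betaine	Amino acids, peptides, and analogues	1	1
CMB018	Proline	Amino acids, peptides, and analogues	1	1
CMB019	Tyrosine	Amino acids, peptides, and analogues	1	1
CMB020	Valine	Amino acids, peptides, and analogues	1	1
CMB021	3-Hydroxyphenylpropionic acid	Phenylpropanoids and polyketides	1	1
CMB022	3-Phenylpropionic acid	Phenylpropanoids and polyketides	1	1
CMB023	3,4-Dihydroxyhydrocinnamic acid	Phenylpropanoids and polyketides	1	1
CMB024	4-Hydroxyphenylpropionic acid	Phenylpropanoids and polyketides	1	1
CMB025	5-Hydroxyequol	Phenylpropanoids and polyketides	1	1
CMB026	Daidzein	Phenylpropanoids and polyketides	1	1
CMB027	Dihydrodaidzein	Phenylpropanoids and polyketides	1	1
CMB028	Dihydroferulic acid	Phenylpropanoids and polyketides	1	1
CMB029	Dihydrogenistein	Phenylpropanoids and polyketides	1	1
CMB030	Equol	Phenylpropanoids and polyketides	1	1
CMB031	Ferulic acid	Phenylpropanoids and polyketides	1	1
CMB032	m-Coumaric acid	Phenylpropanoids and polyketides	1	1
CMB033	O-Desmethylangolensin	Phenylpropanoids and polyketides	1	1
CMB034	Phenyllactic acid	Phenylpropanoids and polyketides	1	1
CMB035	Quercetin	Phenylpropanoids and polyketides	1	1
CMB036	Theaflavin	Phenylpropanoids and polyketides	1	1
CMB037	Theaflavin-3-gallic acid	Phenylpropanoids and polyketides	1	1
CMB038	Theaflavin-3'-gallic acid	Phenylpropanoids and polyketides	1	1
CMB039	2-Methylbutyric acid (5:0)	Fatty Acyls	1	1
CMB040	4-Butyric acid betaine	Fatty Acyls	1	1
CMB041	5-Aminovaleric acid betaine	Fatty Acyls	1	1
CMB042	Behenic acid (22:0)	Fatty Acyls	1	1
CMB043	Butyric acid (4:0)	Fatty Acyls	1	1
CMB044	Caproic acid (6:0)	Fatty Acyls	1	1
CMB045	Isovaleric acid (5:0)	Fatty Acyls	1	1
CMB046	Margaric acid (17:0)	Fatty Acyls	1	1
CMB047	Palmitic acid (16:0)	Fatty Acyls	1	1
CMB048	Palmitoleic acid (cis-16:1n-7)	Fatty Acyls	1	1
CMB049	Valeric acid (5:0)	Fatty Acyls	1	1
CMB050	12-Ketolithocholic acid	Bile acids, alcohols and derivatives	1	1
CMB051	7-Ketolithocholic acid	Bile acids, alcohols and derivatives	1	1
CMB052	Allodeoxycholic acid	Bile acids, alcohols and derivatives	1	1
CMB053	Chenodeoxycholic acid	Bile acids, alcohols and derivatives	1	1
CMB054	Deoxycholic acid	Bile acids, alcohols and derivatives	1	1
CMB055	Isoursodeoxycholic acid	Bile acids, alcohols and derivatives	1	1
CMB056	Lithocholic acid	Bile acids, alcohols and derivatives	1	1
CMB057	1,2-Dihydroxybenzene	Phenols	1	1
CMB058	3-Hydroxyphenylacetic acid	Phenols	1	1
CMB059	3,4-Dihydroxyphenylacetic acid	Phenols	1	1
CMB060	4-Hydroxyphenylacetic acid	Phenols	1	1
CMB061	Dopamine	Phenols	1	1
CMB062	Homovanillic acid	Phenols	1	1
CMB063	p-Cresol	Phenols	1	1
CMB064	Phenol	Phenols	1	1
CMB065	Indole-3-aldehyde	Indoles and derivatives	1	1
CMB066	Indole-3-carboxylic acid	Indoles and derivatives	1	1
CMB067	Indole	Indoles and derivatives	1	1
CMB068	Indoleacetic acid	Indoles and derivatives	1	1
CMB069	Indoleethanol	Indoles and derivatives	1	1
CMB070	Indolelactic acid	Indoles and derivatives	1	1
CMB071	Indolepropionic acid	Indoles and derivatives	1	1
CMB072	Tryptamine	Indoles and derivatives	1	1
CMB073	Tryptophan	Indoles and derivatives	1	1
CMB074	Alanine betaine	Organic nitrogen compounds	1	1
CMB075	Cadaverine	Organic nitrogen compounds	1	1
CMB076	Dimethylamine	Organic nitrogen compounds	1	1
CMB077	Methylamine	Organic nitrogen compounds	1	1
CMB078	Putrescine	Organic nitrogen compounds	1	1
CMB079	Spermidine	Organic nitrogen compounds	1	1
CMB080	Trimethylamine	Organic nitrogen compounds	1	1
CMB081	2,3-Dihydroxybenzoic acid	Benzoic acids and derivatives	1	1
CMB082	Benzoic acid	Benzoic acids and derivatives	1	1
CMB083	Gallic acid	Benzoic acids and derivatives	1	1
CMB084	Hippuric acid	Benzoic acids and derivatives	1	1
CMB085	Protocatechuic acid	Benzoic acids and derivatives	1	1
CMB086	Salicylic acid	Benzoic acids and derivatives	1	1
CMB087	Vanillic acid	Benzoic acids and derivatives	1	1
CMB088	Acetic acid (2:0)	Carboxylic acids and derivatives	1	1
CMB089	Formic acid	Carboxylic acids and derivatives	1	1
CMB090	Fumaric acid	Carboxylic acids and derivatives	1	1
CMB091	Isobutyric acid (4:0)	Carboxylic acids and derivatives	1	1
CMB092	Methylmalonic acid (MMA)	Carboxylic acids and derivatives	1	1
CMB093	Propionic acid (3:0)	Carboxylic acids and derivatives	1	1
CMB094	Succinic acid	Carboxylic acids and derivatives	1	1
CMB095	2-Hydroxyphenylacetic acid	Benzene and substituted derivatives	1	1
CMB096	Phenethylamine	Benzene and substituted derivatives	1	1
CMB097	Phenylacetic acid	Benzene and substituted derivatives	1	1
CMB098	Tyramine	Benzene and substituted derivatives	1	1
CMB099	Lactic acid	Hydroxy acids and derivatives	1	1
CMB100	5beta-Coprostanol	Steroids and steroid derivatives	1	1
CMB101	Stercobilinogen	Tetrapyrroles and derivatives	1	1
CMB102	Urobilin	Tetrapyrroles and derivatives	1	1
CMB103	Urobilinogen	Tetrapyrroles and derivatives	1	1
CMB104	Piperidine	Organoheterocyclic compounds	1	1
CMB105	Folates	Pteridines and derivatives	1	1
CMB106	Riboflavin	Pteridines and derivatives	1	1
CMB107	Enterolactone	Lignans, neolignans and related compounds	1	1
CMB108	Trigonelline	Alkaloids and derivatives	1	1
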