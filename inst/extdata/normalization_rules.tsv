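rule_id	pattern	replacement	anchor
quote_right	’	'	ANYWHERE
quote_left	‘	'	ANYWHERE
quote_mod	ʼ	'	ANYWHERE
dquote_left	“	"	ANYWHERE
dquote_right	”	"	ANYWHERE
endash	–	-	ANYWHERE
emdash	—	-	ANYWHERE
minus	−	-	ANYWHERE
greek_alpha	α	alpha	ANYWHERE
greek_beta	β	beta	ANYWHERE
greek_gamma	γ	gamma	ANYWHERE
greek_delta	δ	delta	ANYWHERE
greek_epsilon	ε	epsilon	ANYWHERE
greek_omega	ω	omega	ANYWHERE
prefix_cis	cis-	z-	PREFIX
prefix_trans	trans-	e-	PREFIX
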