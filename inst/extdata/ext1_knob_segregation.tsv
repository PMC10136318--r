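# Published per-breed genotype-phenotype segregation tallies for four
# candidate EXT1 SNPs (scaffold NW_013185721.1) against the protuberant
# knob phenotype in an extended goose panel: three knobbed Chinese
# indigenous breeds and knobless swan geese. yes = individuals whose
# genotype matches the genotype expected for their phenotype class.
breed	phenotype	n	snp_pos	yes	no
Zhedong	case	17	4792818	17	0
Panshi_grey	case	18	4792818	18	0
Yongkang_grey	case	20	4792818	20	0
Swan_goose	control	7	4792818	7	0
Zhedong	case	17	4793508	17	0
Panshi_grey	case	18	4793508	18	0
Yongkang_grey	case	20	4793508	20	0
Swan_goose	control	7	4793508	7	0
Zhedong	case	17	4796205	17	0
Panshi_grey	case	18	4796205	18	0
Yongkang_grey	case	20	4796205	20	0
Swan_goose	control	7	4796205	5	2
Zhedong	case	17	4806051	13	4
Panshi_grey	case	18	4806051	18	0
Yongkang_grey	case	20	4806051	10	10
Swan_goose	control	7	4806051	2	5
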