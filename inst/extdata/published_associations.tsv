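exposure	outcome	direction	level	or	ci_low	ci_high	pval
Coprococcus3	AP	forward	genus	1.48	1.049	2.089	0.048
Eubacterium fissicatena group	AP	forward	genus	1.24	1.045	1.471	0.013
Prevotella9	AP	forward	genus	0.82	0.68	0.989	0.038
Ruminiclostridium6	AP	forward	genus	0.696	0.548	0.883	0.002
Ruminococcaceae UCG004	AP	forward	genus	0.757	0.576	0.994	0.045
Slackia	AP	forward	genus	0.766	0.59	0.996	0.046
Slackia	CP	forward	genus	0.633	0.449	0.892	0.009
Defluviitaleaceae	CP	forward	family	1.408	1.053	1.883	0.02
Barnesiella	CP	forward	genus	1.484	1.055	2.088	0.023
Defluviitaleaceae UCG011	CP	forward	genus	1.443	1.042	1.998	0.027
Eubacterium xylanophilum group	CP	forward	genus	1.502	1.049	2.15	0.026
Sellimonas	CP	forward	genus	1.219	1.006	1.478	0.042
Flavonifractor	AAP	forward	genus	0.29	0.12	0.71	0.006
Haemophilus	AAP	forward	genus	1.76	1.02	3.037	0.041
Intestinimonas	AAP	forward	genus	1.724	1.017	2.924	0.043
Lachnospiraceae UCG001	AAP	forward	genus	2.011	1.193	3.389	0.008
Sellimonas	AAP	forward	genus	1.673	1.169	2.395	0.004
Oscillibacter	ACP	forward	genus	2.179	1.057	4.449	0.034
Melainabacteria	ACP	forward	class	1.801	1.288	2.519	5e-04
Gastranaerophilales	ACP	forward	order	1.712	1.171	2.503	0.005
Butyricimonas	ACP	forward	genus	1.579	1.001	2.488	0.049
Enterorhabdus	ACP	forward	genus	1.764	1.073	2.902	0.025
Eubacterium oxidoreducens group	ACP	forward	genus	1.602	1.023	2.51	0.039
Eubacterium xylanophilum group	ACP	forward	genus	1.899	1.179	3.06	0.008
Sellimonas	ACP	forward	genus	1.347	1.006	1.803	0.048
Clostridiaceae1	ACP	forward	family	0.563	0.342	0.928	0.024
Slackia	ACP	forward	genus	0.614	0.388	0.971	0.037
Subdoligranulum	ACP	forward	genus	0.561	0.339	0.928	0.024
AP	Proteobacteria	reverse	phylum	1.075	1.003	1.152	0.038
AP	Lachnospiraceae NC2004 group	reverse	genus	1.148	1.033	1.275	0.01
AP	Marvinbryantia	reverse	genus	1.1	1.012	1.196	0.024
AP	Holdemania	reverse	genus	0.914	0.839	0.997	0.043
AP	Oscillospira	reverse	genus	0.919	0.847	0.998	0.045
CP	Prevotella9	reverse	genus	1.067	1.018	1.117	0.006
CP	Firmicutes	reverse	phylum	0.967	0.936	0.999	0.047
CP	Family XIII	reverse	family	0.955	0.921	0.99	0.014
CP	Coprobacter	reverse	genus	0.94	0.889	0.995	0.032
CP	Eubacterium hallii group	reverse	genus	0.952	0.918	0.987	0.008
CP	Fusicatenibacter	reverse	genus	0.955	0.922	0.989	0.011
CP	Slackia	reverse	genus	0.941	0.888	0.998	0.043
AAP	Oscillibacter	reverse	genus	1.045	1.007	1.083	0.017
AAP	Firmicutes	reverse	phylum	0.972	0.948	0.997	0.031
AAP	Tenericutes	reverse	phylum	0.965	0.935	0.997	0.032
AAP	Clostridia	reverse	class	0.973	0.949	0.998	0.036
AAP	Coriobacteriia	reverse	class	0.974	0.949	0.999	0.046
AAP	Mollicutes	reverse	class	0.965	0.935	0.997	0.032
AAP	Coriobacteriaceae	reverse	family	0.974	0.949	0.999	0.046
AAP	Rhodospirillaceae	reverse	family	0.963	0.928	0.999	0.048
AAP	Clostridiales	reverse	order	0.973	0.949	0.998	0.036
AAP	Coriobacteriales	reverse	order	0.974	0.949	0.999	0.046
AAP	Mollicutes RF9	reverse	order	0.962	0.93	0.995	0.024
AAP	Eubacterium xylanophilum group	reverse	genus	0.961	0.933	0.99	0.009
AAP	Ruminiclostridium6	reverse	genus	0.969	0.941	0.998	0.039
AAP	Ruminococcaceae UCG014	reverse	genus	0.953	0.926	0.98	0.001
ACP	Negativicutes	reverse	class	0.971	0.943	0.999	0.046
ACP	Selenomonadales	reverse	order	0.971	0.943	0.999	0.046
ACP	Butyrivibrio	reverse	genus	0.893	0.831	0.96	0.002
ACP	Ruminiclostridium5	reverse	genus	0.96	0.932	0.989	0.007
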