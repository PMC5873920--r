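name	chrom	start	end	category	pseudogene
GNE	9	171979300	172038723	biosynthesis	FALSE
NANS	9	72927011	73006371	biosynthesis	FALSE
NANP	20	138409663	138461789	biosynthesis	FALSE
RENBP	X	107492068	107570302	biosynthesis	FALSE
CMAS	12	162058673	162072762	activation_transport_transfer	FALSE
SLC35A1	6	86623715	86688072	activation_transport_transfer	FALSE
SLC17A5	6	41687108	41802546	activation_transport_transfer	FALSE
ST3GAL1	8	17962873	17981481	activation_transport_transfer	FALSE
ST3GAL2	16	136765149	136798706	activation_transport_transfer	FALSE
ST3GAL3	1	161823609	161936085	activation_transport_transfer	FALSE
ST3GAL4	11	144761004	144854263	activation_transport_transfer	FALSE
ST3GAL5	2	101911329	102030937	activation_transport_transfer	FALSE
ST3GAL6	3	48612848	48682256	activation_transport_transfer	FALSE
ST6GAL1	3	41997125	42080077	activation_transport_transfer	FALSE
ST6GAL2	2	92476994	92563293	activation_transport_transfer	FALSE
ST6GALNAC1	17	185624118	185726070	activation_transport_transfer	FALSE
ST6GALNAC2	17	43580007	43609614	activation_transport_transfer	FALSE
ST6GALNAC3	1	62866086	62946969	activation_transport_transfer	FALSE
ST6GALNAC4	9	111923851	112000282	activation_transport_transfer	FALSE
ST6GALNAC5	1	100241506	100246520	activation_transport_transfer	FALSE
ST6GALNAC6	9	91500827	91619471	activation_transport_transfer	FALSE
ST8SIA1	12	89376283	89487395	activation_transport_transfer	FALSE
ST8SIA2	15	6322647	6353135	activation_transport_transfer	FALSE
ST8SIA3	18	22296749	22415338	activation_transport_transfer	FALSE
ST8SIA4	5	154550996	154651201	activation_transport_transfer	FALSE
ST8SIA5	18	154717137	154745444	activation_transport_transfer	FALSE
ST8SIA6	10	190950239	191059419	activation_transport_transfer	FALSE
SIGLEC1	20	139110236	139178318	recognition	FALSE
CD22	19	198704056	198748604	recognition	FALSE
CD33	19	28979768	29088302	recognition	FALSE
MAG	19	39214940	39260808	recognition	FALSE
SIGLEC5	19	101668556	101727113	recognition	FALSE
SIGLEC6	19	194982937	194997705	recognition	FALSE
SIGLEC7	19	137925943	137956792	recognition	FALSE
SIGLEC8	19	2574770	2624344	recognition	FALSE
SIGLEC9	19	169637038	169719340	recognition	FALSE
SIGLEC10	19	62755690	62838421	recognition	FALSE
SIGLEC11	19	182365104	182467116	recognition	FALSE
SIGLEC12	19	53336545	53424070	recognition	FALSE
SIGLEC14	19	185273678	185363070	recognition	FALSE
SIGLEC15	18	31853307	31932301	recognition	FALSE
SIGLEC16	19	42880985	42893344	recognition	FALSE
SELP	1	44484257	44518275	recognition	FALSE
SELE	1	142193532	142295824	recognition	FALSE
SELL	1	11568315	11681440	recognition	FALSE
LAMA2	6	103698906	103792598	recognition	FALSE
L1CAM	X	185874530	185957218	recognition	FALSE
NCAM1	11	166816501	166888186	recognition	FALSE
CD24	6	104472819	104570969	recognition	FALSE
SPN	16	23056890	23075742	recognition	FALSE
NEU1	6	149055626	149122265	recycling_degradation	FALSE
NEU2	2	94335613	94375394	recycling_degradation	FALSE
NEU3	11	93130427	93170802	recycling_degradation	FALSE
NEU4	2	38527155	38540234	recycling_degradation	FALSE
CTSA	20	1074398	1158371	recycling_degradation	FALSE
SIAE	11	49548108	49627539	recycling_degradation	FALSE
NPL	1	44865650	44962647	recycling_degradation	FALSE
CMAH	6	179544174	179617978	modification	TRUE
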