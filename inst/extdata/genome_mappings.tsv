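genome_id	query_id	query_length_bp	pct_identity
GCA_019702695.1_Acarterae	AT1G14710.1_ALKBH10B	2429	44.2
GCA_019702695.1_Acarterae	AT1G14710.2_ALKBH10B	2513	45.8
GCA_019702695.1_Acarterae	AT1G48980.1_ALKBH9B	1830	48.2
GCA_019702695.1_Acarterae	AT1G48980.2_ALKBH9B	1818	46.6
GCA_019702695.1_Acarterae	AT1G48980.3_ALKBH9B	1832	48.2
GCA_019702695.1_Acarterae	AT1G48980.4_ALKBH9B	1745	48.2
GCA_019702695.1_Acarterae	AT2G17970.1_ALKBH9B	1797	45.1
GCA_019702695.1_Acarterae	AT2G17970.2_ALKBH9B	1981	45.7
GCA_019702695.1_Acarterae	AT2G17970.3_ALKBH9B	2119	45.4
GCA_019702695.1_Acarterae	AT2G48080.1_ALKBH10B	1519	46.7
GCA_019702695.1_Acarterae	AT3G05680.1_VIRILIZER	6833	100
GCA_019702695.1_Acarterae	AT3G05680.2_VIRILIZER	6904	100
GCA_019702695.1_Acarterae	AT3G54170.1_FIP37	1262	45.7
GCA_019702695.1_Acarterae	AT4G02940.1_ALKBH10B	2112	44.4
GCA_019702695.1_Acarterae	AT4G09980.1_MTB	3393	43.4
GCA_019702695.1_Acarterae	AT4G09980.2_MTB	3342	46.5
GCA_019702695.1_Acarterae	AT4G10760.1_MTA	2227	46.9
GCA_019702695.1_Acarterae	AT4G36090.1_ALKBH9B	1830	44.8
GCA_019702695.1_Acarterae	AT4G36090.2_ALKBH9B	2025	100
GCA_019702695.1_Acarterae	AT4G36090.3_ALKBH9B	1707	45.7
GCA_019702695.1_Acarterae	AT5G01160.1_HAKAI	1404	46
GCA_019702695.1_Acarterae	NP_001042682.1_MTB XM_015763885.2	4254	40.5
GCA_019702695.1_Acarterae	NP_001047707.1_MTA XM_015769953.1	2476	45.4
GCA_019702695.1_Acarterae	NP_001048963.2_MTB XM_015776811.2	2832	42.9
GCA_019702695.1_Acarterae	NP_001049502.1_ALKBH10B XM_015775307.2	2532	100
GCA_019702695.1_Acarterae	NP_001056738.1_ALKBH9B XM_015787389.2	2221	46.3
GCA_019702695.1_Acarterae	NP_001057630.2_FIP37 XM_015788828.2	1428	42.6
GCA_019702695.1_Acarterae	NP_001064055.1_ALKBH10B XM_015759337.2	2380	42.5
GCA_019702695.1_Acarterae	NP_001064723.2_MTB XM_015759054.2	3607	100
GCA_019702695.1_Acarterae	NP_001064945.2_HAKAI XM_015758095.2	1685	43.3
GCA_019693525.1_Cfusiformis	AT1G14710.1_ALKBH10B	2429	49.8
GCA_019693525.1_Cfusiformis	AT1G14710.2_ALKBH10B	2513	46.3
GCA_019693525.1_Cfusiformis	AT1G48980.1_ALKBH9B	1830	42
GCA_019693525.1_Cfusiformis	AT1G48980.2_ALKBH9B	1818	42.4
GCA_019693525.1_Cfusiformis	AT1G48980.3_ALKBH9B	1832	42
GCA_019693525.1_Cfusiformis	AT1G48980.4_ALKBH9B	1745	44.9
GCA_019693525.1_Cfusiformis	AT2G17970.1_ALKBH9B	1797	49.7
GCA_019693525.1_Cfusiformis	AT2G17970.2_ALKBH9B	1981	45.1
GCA_019693525.1_Cfusiformis	AT2G17970.3_ALKBH9B	2119	47.6
GCA_019693525.1_Cfusiformis	AT2G48080.1_ALKBH10B	1519	42.1
GCA_019693525.1_Cfusiformis	AT3G05680.1_VIRILIZER	6833	100
GCA_019693525.1_Cfusiformis	AT3G05680.2_VIRILIZER	6904	100
GCA_019693525.1_Cfusiformis	AT3G54170.1_FIP37	1262	44.6
GCA_019693525.1_Cfusiformis	AT4G02940.1_ALKBH10B	2112	42
GCA_019693525.1_Cfusiformis	AT4G09980.1_MTB	3393	100
GCA_019693525.1_Cfusiformis	AT4G09980.2_MTB	3342	100
GCA_019693525.1_Cfusiformis	AT4G10760.1_MTA	2227	84.6
GCA_019693525.1_Cfusiformis	AT4G36090.1_ALKBH9B	1830	46.7
GCA_019693525.1_Cfusiformis	AT4G36090.2_ALKBH9B	2025	46.9
GCA_019693525.1_Cfusiformis	AT4G36090.3_ALKBH9B	1707	46.6
GCA_019693525.1_Cfusiformis	AT5G01160.1_HAKAI	1404	43.1
GCA_019693525.1_Cfusiformis	NP_001047707.1_MTA XM_015769953.1	2476	45.6
GCA_019693525.1_Cfusiformis	NP_001049502.1_ALKBH10B XM_015775307.2	2532	40.6
GCA_019693525.1_Cfusiformis	NP_001056738.1_ALKBH9B XM_015787389.2	2221	53
GCA_019693525.1_Cfusiformis	NP_001057630.2_FIP37 XM_015788828.2	1428	40.5
GCA_019693525.1_Cfusiformis	NP_001064055.1_ALKBH10B XM_015759337.2	2380	47
GCA_019693525.1_Cfusiformis	NP_001064723.2_MTB XM_015759054.2	3607	40.4
GCA_019693525.1_Cfusiformis	NP_001064945.2_HAKAI XM_015758095.2	1685	42.5
GCA_006384855.1_Tstriata	AT1G14710.1_ALKBH10B	2429	40.5
GCA_006384855.1_Tstriata	AT1G14710.2_ALKBH10B	2513	40.5
GCA_006384855.1_Tstriata	AT1G48980.1_ALKBH9B	1830	43.7
GCA_006384855.1_Tstriata	AT1G48980.3_ALKBH9B	1832	43.7
GCA_006384855.1_Tstriata	AT1G48980.4_ALKBH9B	1745	43.7
GCA_006384855.1_Tstriata	AT2G48080.1_ALKBH10B	1519	44
GCA_006384855.1_Tstriata	AT3G05680.1_VIRILIZER	6833	100
GCA_006384855.1_Tstriata	AT3G05680.2_VIRILIZER	6904	100
GCA_006384855.1_Tstriata	AT3G54170.1_FIP37	1262	42
GCA_006384855.1_Tstriata	AT4G10760.1_MTA	2227	42.4
GCA_006384855.1_Tstriata	AT4G36090.1_ALKBH9B	1830	46.7
GCA_006384855.1_Tstriata	AT4G36090.2_ALKBH9B	2025	46.1
GCA_006384855.1_Tstriata	AT4G36090.3_ALKBH9B	1707	46.1
GCA_006384855.1_Tstriata	AT5G01160.1_HAKAI	1404	42.6
GCA_006384855.1_Tstriata	NP_001042682.1_MTB XM_015763885.2	4254	100
GCA_006384855.1_Tstriata	NP_001047707.1_MTA XM_015769953.1	2476	48.8
GCA_006384855.1_Tstriata	NP_001048963.2_MTB XM_015776811.2	2832	40.9
GCA_006384855.1_Tstriata	NP_001056738.1_ALKBH9B XM_015787389.2	2221	42.9
GCA_006384855.1_Tstriata	NP_001057630.2_FIP37 XM_015788828.2	1428	45
GCA_006384855.1_Tstriata	NP_001064055.1_ALKBH10B XM_015759337.2	2380	45.9
GCA_006384855.1_Tstriata	NP_001064945.2_HAKAI XM_015758095.2	1685	48.3
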