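# Synthetic CFD-style mismatch penalty table (NOT the published CFD values).
# Generated deterministically: identity pairs = 1.0; mismatches =
#   w * (1 - 0.045*(position-1)), w = 0.6 for transition-like pairs
#   (purine-purine / pyrimidine-pyrimidine), 0.35 for transversions.
# Positions 1..20 counted from the PAM-distal end (20 = PAM-proximal).
# provenance: synthetic, motifguides package
guide_base	site_base	position	penalty
A	A	1	1.0000
A	A	2	1.0000
A	A	3	1.0000
A	A	4	1.0000
A	A	5	1.0000
A	A	6	1.0000
A	A	7	1.0000
A	A	8	1.0000
A	A	9	1.0000
A	A	10	1.0000
A	A	11	1.0000
A	A	12	1.0000
A	A	13	1.0000
A	A	14	1.0000
A	A	15	1.0000
A	A	16	1.0000
A	A	17	1.0000
A	A	18	1.0000
A	A	19	1.0000
A	A	20	1.0000
A	C	1	0.3500
A	C	2	0.3342
A	C	3	0.3185
A	C	4	0.3027
A	C	5	0.2870
A	C	6	0.2712
A	C	7	0.2555
A	C	8	0.2397
A	C	9	0.2240
A	C	10	0.2082
A	C	11	0.1925
A	C	12	0.1767
A	C	13	0.1610
A	C	14	0.1452
A	C	15	0.1295
A	C	16	0.1138
A	C	17	0.0980
A	C	18	0.0822
A	C	19	0.0665
A	C	20	0.0508
A	G	1	0.6000
A	G	2	0.5730
A	G	3	0.5460
A	G	4	0.5190
A	G	5	0.4920
A	G	6	0.4650
A	G	7	0.4380
A	G	8	0.4110
A	G	9	0.3840
A	G	10	0.3570
A	G	11	0.3300
A	G	12	0.3030
A	G	13	0.2760
A	G	14	0.2490
A	G	15	0.2220
A	G	16	0.1950
A	G	17	0.1680
A	G	18	0.1410
A	G	19	0.1140
A	G	20	0.0870
A	T	1	0.3500
A	T	2	0.3342
A	T	3	0.3185
A	T	4	0.3027
A	T	5	0.2870
A	T	6	0.2712
A	T	7	0.2555
A	T	8	0.2397
A	T	9	0.2240
A	T	10	0.2082
A	T	11	0.1925
A	T	12	0.1767
A	T	13	0.1610
A	T	14	0.1452
A	T	15	0.1295
A	T	16	0.1138
A	T	17	0.0980
A	T	18	0.0822
A	T	19	0.0665
A	T	20	0.0508
C	A	1	0.3500
C	A	2	0.3342
C	A	3	0.3185
C	A	4	0.3027
C	A	5	0.2870
C	A	6	0.2712
C	A	7	0.2555
C	A	8	0.2397
C	A	9	0.2240
C	A	10	0.2082
C	A	11	0.1925
C	A	12	0.1767
C	A	13	0.1610
C	A	14	0.1452
C	A	15	0.1295
C	A	16	0.1138
C	A	17	0.0980
C	A	18	0.0822
C	A	19	0.0665
C	A	20	0.0508
C	C	1	1.0000
C	C	2	1.0000
C	C	3	1.0000
C	C	4	1.0000
C	C	5	1.0000
C	C	6	1.0000
C	C	7	1.0000
C	C	8	1.0000
C	C	9	1.0000
C	C	10	1.0000
C	C	11	1.0000
C	C	12	1.0000
C	C	13	1.0000
C	C	14	1.0000
C	C	15	1.0000
C	C	16	1.0000
C	C	17	1.0000
C	C	18	1.0000
C	C	19	1.0000
C	C	20	1.0000
C	G	1	0.3500
C	G	2	0.3342
C	G	3	0.3185
C	G	4	0.3027
C	G	5	0.2870
C	G	6	0.2712
C	G	7	0.2555
C	G	8	0.2397
C	G	9	0.2240
C	G	10	0.2082
C	G	11	0.1925
C	G	12	0.1767
C	G	13	0.1610
C	G	14	0.1452
C	G	15	0.1295
C	G	16	0.1138
C	G	17	0.0980
C	G	18	0.0822
C	G	19	0.0665
C	G	20	0.0508
C	T	1	0.6000
C	T	2	0.5730
C	T	3	0.5460
C	T	4	0.5190
C	T	5	0.4920
C	T	6	0.4650
C	T	7	0.4380
C	T	8	0.4110
C	T	9	0.3840
C	T	10	0.3570
C	T	11	0.3300
C	T	12	0.3030
C	T	13	0.2760
C	T	14	0.2490
C	T	15	0.2220
C	T	16	0.1950
C	T	17	0.1680
C	T	18	0.1410
C	T	19	0.1140
C	T	20	0.0870
G	A	1	0.6000
G	A	2	0.5730
G	A	3	0.5460
G	A	4	0.5190
G	A	5	0.4920
G	A	6	0.4650
G	A	7	0.4380
G	A	8	0.4110
G	A	9	0.3840
G	A	10	0.3570
G	A	11	0.3300
G	A	12	0.3030
G	A	13	0.2760
G	A	14	0.2490
G	A	15	0.2220
G	A	16	0.1950
G	A	17	0.1680
G	A	18	0.1410
G	A	19	0.1140
G	A	20	0.0870
G	C	1	0.3500
G	C	2	0.3342
G	C	3	0.3185
G	C	4	0.3027
G	C	5	0.2870
G	C	6	0.2712
G	C	7	0.2555
G	C	8	0.2397
G	C	9	0.2240
G	C	10	0.2082
G	C	11	0.1925
G	C	12	0.1767
G	C	13	0.1610
G	C	14	0.1452
G	C	15	0.1295
G	C	16	0.1138
G	C	17	0.0980
G	C	18	0.0822
G	C	19	0.0665
G	C	20	0.0508
G	G	1	1.0000
G	G	2	1.0000
G	G	3	1.0000
G	G	4	1.0000
G	G	5	1.0000
G	G	6	1.0000
G	G	7	1.0000
G	G	8	1.0000
G	G	9	1.0000
G	G	10	1.0000
G	G	11	1.0000
G	G	12	1.0000
G	G	13	1.0000
G	G	14	1.0000
G	G	15	1.0000
G	G	16	1.0000
G	G	17	1.0000
G	G	18	1.0000
G	G	19	1.0000
G	G	20	1.0000
G	T	1	0.3500
G	T	2	0.3342
G	T	3	0.3185
G	T	4	0.3027
G	T	5	0.2870
G	T	6	0.2712
G	T	7	0.2555
G	T	8	0.2397
G	T	9	0.2240
G	T	10	0.2082
G	T	11	0.1925
G	T	12	0.1767
G	T	13	0.1610
G	T	14	0.1452
G	T	15	0.1295
G	T	16	0.1138
G	T	17	0.0980
G	T	18	0.0822
G	T	19	0.0665
G	T	20	0.0508
T	A	1	0.3500
T	A	2	0.3342
T	A	3	0.3185
T	A	4	0.3027
T	A	5	0.2870
T	A	6	0.2712
T	A	7	0.2555
T	A	8	0.2397
T	A	9	0.2240
T	A	10	0.2082
T	A	11	0.1925
T	A	12	0.1767
T	A	13	0.1610
T	A	14	0.1452
T	A	15	0.1295
T	A	16	0.1138
T	A	17	0.0980
T	A	18	0.0822
T	A	19	0.0665
T	A	20	0.0508
T	C	1	0.6000
T	C	2	0.5730
T	C	3	0.5460
T	C	4	0.5190
T	C	5	0.4920
T	C	6	0.4650
T	C	7	0.4380
T	C	8	0.4110
T	C	9	0.3840
T	C	10	0.3570
T	C	11	0.3300
T	C	12	0.3030
T	C	13	0.2760
T	C	14	0.2490
T	C	15	0.2220
T	C	16	0.1950
T	C	17	0.1680
T	C	18	0.1410
T	C	19	0.1140
T	C	20	0.0870
T	G	1	0.3500
T	G	2	0.3342
T	G	3	0.3185
T	G	4	0.3027
T	G	5	0.2870
T	G	6	0.2712
T	G	7	0.2555
T	G	8	0.2397
T	G	9	0.2240
T	G	10	0.2082
T	G	11	0.1925
T	G	12	0.1767
T	G	13	0.1610
T	G	14	0.1452
T	G	15	0.1295
T	G	16	0.1138
T	G	17	0.0980
T	G	18	0.0822
T	G	19	0.0665
T	G	20	0.0508
T	T	1	1.0000
T	T	2	1.0000
T	T	3	1.0000
T	T	4	1.0000
T	T	5	1.0000
T	T	6	1.0000
T	T	7	1.0000
T	T	8	1.0000
T	T	9	1.0000
T	T	10	1.0000
T	T	11	1.0000
T	T	12	1.0000
T	T	13	1.0000
T	T	14	1.0000
T	T	15	1.0000
T	T	16	1.0000
T	T	17	1.0000
T	T	18	1.0000
T	T	19	1.0000
T	T	20	1.0000
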