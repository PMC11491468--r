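probe_id	region_id	role	threshold
2q36_p1	2q36	classification	2
2q36_p2	2q36	classification	2
2q36_p3	2q36	classification	2
2q36_p4	2q36	classification	2
3q26_p1	3q26	classification	3
3q26_p2	3q26	classification	3
3q26_p3	3q26	classification	3
3q26_p4	3q26	classification	3
4q35_p1	4q35	classification	2
4q35_p2	4q35	classification	2
4q35_p3	4q35	classification	2
4q35_p4	4q35	classification	2
5q15_p1	5q15	classification	2
5q15_p2	5q15	classification	2
5q15_p3	5q15	classification	2
7p11_p1	7p11	classification	2
7p11_p2	7p11	classification	2
7p11_p3	7p11	classification	2
7p11_p4	7p11	classification	2
8q11_p1	8q11	classification	2
8q11_p2	8q11	classification	2
8q11_p3	8q11	classification	2
9p22_p1	9p22	classification	2
9p22_p2	9p22	classification	2
9p22_p3	9p22	classification	2
9p22_p4	9p22	classification	2
11q13_p1	11q13	classification	3
11q13_p2	11q13	classification	3
11q13_p3	11q13	classification	3
11q13_p4	11q13	classification	3
18p11_p1	18p11	classification	2
18p11_p2	18p11	classification	2
18p11_p3	18p11	classification	2
20q11_p1	20q11	classification	2
20q11_p2	20q11	classification	2
20q11_p3	20q11	classification	2
ref_p01	reference	reference	NA
ref_p02	reference	reference	NA
ref_p03	reference	reference	NA
ref_p04	reference	reference	NA
ref_p05	reference	reference	NA
ref_p06	reference	reference	NA
ref_p07	reference	reference	NA
ref_p08	reference	reference	NA
ref_p09	reference	reference	NA
ref_p10	reference	reference	NA
ref_p11	reference	reference	NA
ref_p12	reference	reference	NA
ref_p13	reference	reference	NA
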