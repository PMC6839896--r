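individual	mother	generation	site	allele_ratio_percent
F0_001	NA	F0	mt.T5718G	3.75
F0_002	NA	F0	mt.T5718G	4.5
F0_003	NA	F0	mt.T5718G	12.3
F0_004	NA	F0	mt.T5718G	21.8
F0_005	NA	F0	mt.T5718G	30.6
F0_006	NA	F0	mt.T5718G	38.2
F0_007	NA	F0	mt.T5718G	45.1
F0_008	NA	F0	mt.T5718G	52.7
F0_009	NA	F0	mt.T5718G	58.4
F0_010	NA	F0	mt.T5718G	63.9
F0_011	NA	F0	mt.T5718G	70.2
F0_012	NA	F0	mt.T5718G	76.8
F0_013	NA	F0	mt.T5718G	81.5
F0_014	NA	F0	mt.T5718G	86.3
F0_015	NA	F0	mt.T5718G	90.7
F0_016	NA	F0	mt.T5718G	94.2
F0_017	NA	F0	mt.T5718G	97.1
F0_018	NA	F0	mt.T5718G	100
F0_019	NA	F0	mt.T5718G	100
F0_020	NA	F0	mt.T5718G	100
F0_021	NA	F0	mt.T5718G	100
F0_022	NA	F0	mt.T5718G	100
F0_023	NA	F0	mt.T5718G	100
F0_024	NA	F0	mt.T5718G	100
F0_025	NA	F0	mt.T5718G	100
F0_026	NA	F0	mt.T5718G	100
F1_001_1	F0_001	F1	mt.T5718G	100
F1_001_2	F0_001	F1	mt.T5718G	100
F1_001_3	F0_001	F1	mt.T5718G	100
F1_001_4	F0_001	F1	mt.T5718G	100
F1_002_1	F0_002	F1	mt.T5718G	100
F1_002_2	F0_002	F1	mt.T5718G	100
F1_002_3	F0_002	F1	mt.T5718G	100
F1_002_4	F0_002	F1	mt.T5718G	100
F1_003_1	F0_003	F1	mt.T5718G	100
F1_003_2	F0_003	F1	mt.T5718G	100
F1_003_3	F0_003	F1	mt.T5718G	100
F1_004_1	F0_004	F1	mt.T5718G	100
F1_004_2	F0_004	F1	mt.T5718G	100
F1_004_3	F0_004	F1	mt.T5718G	100
F1_005_1	F0_005	F1	mt.T5718G	100
F1_005_2	F0_005	F1	mt.T5718G	100
F1_005_3	F0_005	F1	mt.T5718G	100
F1_006_1	F0_006	F1	mt.T5718G	100
F1_006_2	F0_006	F1	mt.T5718G	100
F1_006_3	F0_006	F1	mt.T5718G	100
F1_007_1	F0_007	F1	mt.T5718G	100
F1_007_2	F0_007	F1	mt.T5718G	100
F1_007_3	F0_007	F1	mt.T5718G	100
F1_008_1	F0_008	F1	mt.T5718G	100
F1_008_2	F0_008	F1	mt.T5718G	100
F1_008_3	F0_008	F1	mt.T5718G	100
F1_009_1	F0_009	F1	mt.T5718G	100
F1_009_2	F0_009	F1	mt.T5718G	100
F1_009_3	F0_009	F1	mt.T5718G	100
F1_010_1	F0_010	F1	mt.T5718G	100
F1_010_2	F0_010	F1	mt.T5718G	100
F1_010_3	F0_010	F1	mt.T5718G	100
F1_011_1	F0_011	F1	mt.T5718G	100
F1_011_2	F0_011	F1	mt.T5718G	100
F1_011_3	F0_011	F1	mt.T5718G	100
F1_012_1	F0_012	F1	mt.T5718G	100
F1_012_2	F0_012	F1	mt.T5718G	100
F1_012_3	F0_012	F1	mt.T5718G	100
F1_013_1	F0_013	F1	mt.T5718G	100
F1_013_2	F0_013	F1	mt.T5718G	100
F1_013_3	F0_013	F1	mt.T5718G	100
F1_014_1	F0_014	F1	mt.T5718G	100
F1_014_2	F0_014	F1	mt.T5718G	100
F1_014_3	F0_014	F1	mt.T5718G	100
F1_015_1	F0_015	F1	mt.T5718G	100
F1_015_2	F0_015	F1	mt.T5718G	100
F1_015_3	F0_015	F1	mt.T5718G	100
F1_016_1	F0_016	F1	mt.T5718G	100
F1_016_2	F0_016	F1	mt.T5718G	100
F1_016_3	F0_016	F1	mt.T5718G	100
F1_017_1	F0_017	F1	mt.T5718G	100
F1_017_2	F0_017	F1	mt.T5718G	100
F1_017_3	F0_017	F1	mt.T5718G	85
F0_001	NA	F0	mt.A5694T	3.75
F0_002	NA	F0	mt.A5694T	4.5
F0_003	NA	F0	mt.A5694T	12.3
F0_004	NA	F0	mt.A5694T	21.8
F0_005	NA	F0	mt.A5694T	30.6
F0_006	NA	F0	mt.A5694T	38.2
F0_007	NA	F0	mt.A5694T	45.1
F0_008	NA	F0	mt.A5694T	52.7
F0_009	NA	F0	mt.A5694T	58.4
F0_010	NA	F0	mt.A5694T	63.9
F0_011	NA	F0	mt.A5694T	70.2
F0_012	NA	F0	mt.A5694T	76.8
F0_013	NA	F0	mt.A5694T	81.5
F0_014	NA	F0	mt.A5694T	86.3
F0_015	NA	F0	mt.A5694T	90.7
F0_016	NA	F0	mt.A5694T	94.2
F0_017	NA	F0	mt.A5694T	97.1
F0_018	NA	F0	mt.A5694T	100
F0_019	NA	F0	mt.A5694T	100
F0_020	NA	F0	mt.A5694T	100
F0_021	NA	F0	mt.A5694T	100
F0_022	NA	F0	mt.A5694T	100
F0_023	NA	F0	mt.A5694T	100
F0_024	NA	F0	mt.A5694T	100
F0_025	NA	F0	mt.A5694T	100
F0_026	NA	F0	mt.A5694T	100
F1_001_1	F0_001	F1	mt.A5694T	100
F1_001_2	F0_001	F1	mt.A5694T	100
F1_001_3	F0_001	F1	mt.A5694T	100
F1_001_4	F0_001	F1	mt.A5694T	100
F1_002_1	F0_002	F1	mt.A5694T	100
F1_002_2	F0_002	F1	mt.A5694T	100
F1_002_3	F0_002	F1	mt.A5694T	100
F1_002_4	F0_002	F1	mt.A5694T	100
F1_003_1	F0_003	F1	mt.A5694T	100
F1_003_2	F0_003	F1	mt.A5694T	100
F1_003_3	F0_003	F1	mt.A5694T	100
F1_004_1	F0_004	F1	mt.A5694T	100
F1_004_2	F0_004	F1	mt.A5694T	100
F1_004_3	F0_004	F1	mt.A5694T	100
F1_005_1	F0_005	F1	mt.A5694T	100
F1_005_2	F0_005	F1	mt.A5694T	100
F1_005_3	F0_005	F1	mt.A5694T	100
F1_006_1	F0_006	F1	mt.A5694T	100
F1_006_2	F0_006	F1	mt.A5694T	100
F1_006_3	F0_006	F1	mt.A5694T	100
F1_007_1	F0_007	F1	mt.A5694T	100
F1_007_2	F0_007	F1	mt.A5694T	100
F1_007_3	F0_007	F1	mt.A5694T	100
F1_008_1	F0_008	F1	mt.A5694T	100
F1_008_2	F0_008	F1	mt.A5694T	100
F1_008_3	F0_008	F1	mt.A5694T	100
F1_009_1	F0_009	F1	mt.A5694T	100
F1_009_2	F0_009	F1	mt.A5694T	100
F1_009_3	F0_009	F1	mt.A5694T	100
F1_010_1	F0_010	F1	mt.A5694T	100
F1_010_2	F0_010	F1	mt.A5694T	100
F1_010_3	F0_010	F1	mt.A5694T	100
F1_011_1	F0_011	F1	mt.A5694T	100
F1_011_2	F0_011	F1	mt.A5694T	100
F1_011_3	F0_011	F1	mt.A5694T	100
F1_012_1	F0_012	F1	mt.A5694T	100
F1_012_2	F0_012	F1	mt.A5694T	100
F1_012_3	F0_012	F1	mt.A5694T	100
F1_013_1	F0_013	F1	mt.A5694T	100
F1_013_2	F0_013	F1	mt.A5694T	100
F1_013_3	F0_013	F1	mt.A5694T	100
F1_014_1	F0_014	F1	mt.A5694T	100
F1_014_2	F0_014	F1	mt.A5694T	100
F1_014_3	F0_014	F1	mt.A5694T	100
F1_015_1	F0_015	F1	mt.A5694T	100
F1_015_2	F0_015	F1	mt.A5694T	100
F1_015_3	F0_015	F1	mt.A5694T	100
F1_016_1	F0_016	F1	mt.A5694T	100
F1_016_2	F0_016	F1	mt.A5694T	85
F1_016_3	F0_016	F1	mt.A5694T	2.1
F1_017_1	F0_017	F1	mt.A5694T	96.5
F1_017_2	F0_017	F1	mt.A5694T	7.7
F1_017_3	F0_017	F1	mt.A5694T	91.2
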