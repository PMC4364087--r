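model	term	coefficient	se	ci_low	ci_high
ols_model3	physical	0.00651	0.00141	0.0037	0.0091
ols_model3	role	0.00287	0.00057	0.0017	0.0040
ols_model3	emotion	0.00693	0.00211	0.0028	0.0110
ols_model3	vitality	0.00127	0.00062	0.0001	0.0025
ols_model3	eat	0.00154	0.00053	0.0005	0.0026
ols_model3	weight	-0.00058	0.00028	-0.0011	-0.00003
ols_model3	digest	0.00094	0.00044	0.0001	0.0018
ols_model3	physical_sq	-0.00004	0.00001	-0.0001	-0.00002
ols_model3	emotion_sq	-0.00004	0.00002	-0.0001	-0.00001
ols_model3	constant	-0.09898	0.06297	-0.2178	0.0296
tpm_model3_part1	physical	0.02836	0.00834	0.0113	0.0449
tpm_model3_part1	role	0.03285	0.01221	0.0114	0.0583
tpm_model3_part1	emotion	0.04287	0.01020	0.0247	0.0637
tpm_model3_part1	constant	NA	NA	NA	NA
tpm_model3_part2	physical	0.00615	0.00188	0.0027	0.0101
tpm_model3_part2	role	0.00336	0.00075	0.0019	0.0048
tpm_model3_part2	emotion	0.00821	0.00277	0.0029	0.0134
tpm_model3_part2	vitality	0.00592	0.00257	0.0009	0.0112
tpm_model3_part2	eat	0.00206	0.00067	0.0008	0.0034
tpm_model3_part2	weight	-0.00090	0.00040	-0.0017	-0.0001
tpm_model3_part2	digest	0.00106	0.00061	-0.0001	0.0023
tpm_model3_part2	physical_sq	-0.00004	0.00002	-0.0001	-0.00001
tpm_model3_part2	vitality_sq	-0.00005	0.00003	-0.0001	0.000003
tpm_model3_part2	emotion_sq	-0.00006	0.00003	-0.0001	-0.00001
tpm_model3_part2	constant	-0.22122	0.07169	-0.3604	-0.0790
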