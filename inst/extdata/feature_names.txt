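content_H
content_E
content_C
entropy_SS
NumSeg_H
NumSeg_E
NumSeg_C
NumSeg_SS
content_Bd
content_Ed
entropy_RSA
RSA_Bd
RSA_Ed
max_RSA_slide_5
min_RSA_slide_5
max_RSA_slide_6
min_RSA_slide_6
max_RSA_slide_7
min_RSA_slide_7
max_RSA_slide_8
min_RSA_slide_8
max_RSA_slide_9
min_RSA_slide_9
max_RSA_slide_10
min_RSA_slide_10
max_RSA_slide_11
min_RSA_slide_11
max_RSA_slide_12
min_RSA_slide_12
max_RSA_slide_13
min_RSA_slide_13
max_RSA_slide_14
min_RSA_slide_14
max_RSA_slide_15
min_RSA_slide_15
max_RSA_slide_16
min_RSA_slide_16
max_RSA_slide_17
min_RSA_slide_17
max_RSA_slide_18
min_RSA_slide_18
avg_RAAP
sd_RAAP
max_RAAP_slide_5
min_RAAP_slide_5
max_RAAP_slide_6
min_RAAP_slide_6
max_RAAP_slide_7
min_RAAP_slide_7
max_RAAP_slide_8
min_RAAP_slide_8
max_RAAP_slide_9
min_RAAP_slide_9
max_RAAP_slide_10
min_RAAP_slide_10
max_RAAP_slide_11
min_RAAP_slide_11
max_RAAP_slide_12
min_RAAP_slide_12
max_RAAP_slide_13
min_RAAP_slide_13
max_RAAP_slide_14
min_RAAP_slide_14
max_RAAP_slide_15
min_RAAP_slide_15
max_RAAP_slide_16
min_RAAP_slide_16
max_RAAP_slide_17
min_RAAP_slide_17
max_RAAP_slide_18
min_RAAP_slide_18
avg_CON
max_CON_slide_5
min_CON_slide_5
max_CON_slide_6
min_CON_slide_6
max_CON_slide_7
min_CON_slide_7
max_CON_slide_8
min_CON_slide_8
max_CON_slide_9
min_CON_slide_9
max_CON_slide_10
min_CON_slide_10
max_CON_slide_11
min_CON_slide_11
max_CON_slide_12
min_CON_slide_12
max_CON_slide_13
min_CON_slide_13
max_CON_slide_14
min_CON_slide_14
max_CON_slide_15
min_CON_slide_15
max_CON_slide_16
min_CON_slide_16
max_CON_slide_17
min_CON_slide_17
max_CON_slide_18
min_CON_slide_18
Num_H_Bd
Num_H_Ed
Num_E_Bd
Num_E_Ed
Num_C_Bd
Num_C_Ed
RSA_H
RSA_E
RSA_C
RSA_max_segment_H
RSA_max_segment_E
RSA_max_segment_C
CON_H
CON_E
CON_C
CON_max_segment_H
CON_max_segment_E
CON_max_segment_C
RAAP_H
RAAP_E
RAAP_C
RAAP_max_segment_H
RAAP_max_segment_E
RAAP_max_segment_C
RAAP_Bd
RAAP_Ed
avg_RAAP_max_RSA_slide_5
avg_RAAP_min_RSA_slide_5
avg_RAAP_max_RSA_slide_6
avg_RAAP_min_RSA_slide_6
avg_RAAP_max_RSA_slide_7
avg_RAAP_min_RSA_slide_7
avg_RAAP_max_RSA_slide_8
avg_RAAP_min_RSA_slide_8
avg_RAAP_max_RSA_slide_9
avg_RAAP_min_RSA_slide_9
avg_RAAP_max_RSA_slide_10
avg_RAAP_min_RSA_slide_10
avg_RAAP_max_RSA_slide_11
avg_RAAP_min_RSA_slide_11
avg_RAAP_max_RSA_slide_12
avg_RAAP_min_RSA_slide_12
avg_RAAP_max_RSA_slide_13
avg_RAAP_min_RSA_slide_13
avg_RAAP_max_RSA_slide_14
avg_RAAP_min_RSA_slide_14
avg_RAAP_max_RSA_slide_15
avg_RAAP_min_RSA_slide_15
avg_RAAP_max_RSA_slide_16
avg_RAAP_min_RSA_slide_16
avg_RAAP_max_RSA_slide_17
avg_RAAP_min_RSA_slide_17
avg_RAAP_max_RSA_slide_18
avg_RAAP_min_RSA_slide_18
avg_RAAP_max_CON_slide_5
avg_RAAP_min_CON_slide_5
avg_RAAP_max_CON_slide_6
avg_RAAP_min_CON_slide_6
avg_RAAP_max_CON_slide_7
avg_RAAP_min_CON_slide_7
avg_RAAP_max_CON_slide_8
avg_RAAP_min_CON_slide_8
avg_RAAP_max_CON_slide_9
avg_RAAP_min_CON_slide_9
avg_RAAP_max_CON_slide_10
avg_RAAP_min_CON_slide_10
avg_RAAP_max_CON_slide_11
avg_RAAP_min_CON_slide_11
avg_RAAP_max_CON_slide_12
avg_RAAP_min_CON_slide_12
avg_RAAP_max_CON_slide_13
avg_RAAP_min_CON_slide_13
avg_RAAP_max_CON_slide_14
avg_RAAP_min_CON_slide_14
avg_RAAP_max_CON_slide_15
avg_RAAP_min_CON_slide_15
avg_RAAP_max_CON_slide_16
avg_RAAP_min_CON_slide_16
avg_RAAP_max_CON_slide_17
avg_RAAP_min_CON_slide_17
avg_RAAP_max_CON_slide_18
avg_RAAP_min_CON_slide_18
RAAP_H_Bd
RAAP_H_Ed
RAAP_E_Bd
RAAP_E_Ed
RAAP_C_Bd
RAAP_C_Ed
max_similarity_epitope_1
max_similarity_epitope_2
max_similarity_epitope_3
max_similarity_epitope_4
max_similarity_epitope_5
max_similarity_non_epitope_1
max_similarity_non_epitope_2
max_similarity_non_epitope_3
max_similarity_non_epitope_4
max_similarity_non_epitope_5
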