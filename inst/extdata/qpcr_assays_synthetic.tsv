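assay_id	well_role	ct
cnv_dup_a	segment_target	21.02
cnv_dup_a	segment_target	20.95
cnv_dup_a	segment_target	21.08
cnv_dup_a	reference_target	20.01
cnv_dup_a	reference_target	19.97
cnv_dup_a	reference_target	20.05
cnv_dup_a	segment_control	22.99
cnv_dup_a	segment_control	23.06
cnv_dup_a	segment_control	22.94
cnv_dup_a	reference_control	20.03
cnv_dup_a	reference_control	19.99
cnv_dup_a	reference_control	20.02
cnv_del_b	segment_target	25.97
cnv_del_b	segment_target	26.05
cnv_del_b	segment_target	26.01
cnv_del_b	reference_target	19.98
cnv_del_b	reference_target	20.04
cnv_del_b	reference_target	20.00
cnv_del_b	segment_control	24.02
cnv_del_b	segment_control	23.95
cnv_del_b	segment_control	24.04
cnv_del_b	reference_control	20.01
cnv_del_b	reference_control	19.96
cnv_del_b	reference_control	20.03
cnv_norm_c	segment_target	23.48
cnv_norm_c	segment_target	23.55
cnv_norm_c	segment_target	23.51
cnv_norm_c	reference_target	21.02
cnv_norm_c	reference_target	20.98
cnv_norm_c	reference_target	21.04
cnv_norm_c	segment_control	24.49
cnv_norm_c	segment_control	24.54
cnv_norm_c	segment_control	24.46
cnv_norm_c	reference_control	22.00
cnv_norm_c	reference_control	22.03
cnv_norm_c	reference_control	21.98
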