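sample_id	mz	intensity	snr	width
C_vulgaris_UTEX395	2636	NA	NA	NA
C_vulgaris_UTEX395	6030	NA	NA	NA
C_vulgaris_UTEX395	6422	NA	NA	NA
C_vulgaris_UTEX395	6451	NA	NA	NA
C_vulgaris_UTEX395	10684	NA	NA	NA
S_acutus_LRB-AP401	2712	NA	NA	NA
S_acutus_LRB-AP401	2735	NA	NA	NA
C_sorokiniana_UTEX1230	2908	NA	NA	NA
C_sorokiniana_UTEX1230	4608	NA	NA	NA
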