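sample_id	mz	intensity	snr	width
mixture1	2636	NA	NA	NA
mixture1	2712	NA	NA	NA
mixture1	6030	NA	NA	NA
mixture1	6422	NA	NA	NA
mixture1	6451	NA	NA	NA
mixture1	6481	NA	NA	NA
mixture1	10684	NA	NA	NA
mixture1	11048	NA	NA	NA
mixture1	11230	NA	NA	NA
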