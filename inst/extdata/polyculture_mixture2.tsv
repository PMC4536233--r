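sample_id	mz	intensity	snr	width
mixture2	2636	NA	NA	NA
mixture2	2712	NA	NA	NA
mixture2	2908	NA	NA	NA
mixture2	4608	NA	NA	NA
mixture2	6030	NA	NA	NA
mixture2	6422	NA	NA	NA
mixture2	6451	NA	NA	NA
mixture2	6481	NA	NA	NA
mixture2	10684	NA	NA	NA
mixture2	11048	NA	NA	NA
mixture2	11230	NA	NA	NA
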