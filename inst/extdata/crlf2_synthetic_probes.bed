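chrX	1187550	1187568	CRLF2_FAM
chrX	1187568	1187588	CRLF2_TAMRA
chrX	1187610	1187630	CRLF2_Cy5
chrX	1187640	1187665	CRLF2_REF
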