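{"name":"CRLF2_ABC_synthetic","probes":[{"name":"CRLF2_FAM","dye":"FAM","role":"dropoff","chrom":"chrX","start":1187550,"end":1187568,"cpg":1187558},{"name":"CRLF2_TAMRA","dye":"TAMRA","role":"dropoff","chrom":"chrX","start":1187568,"end":1187588,"cpg":1187574},{"name":"CRLF2_Cy5","dye":"Cy5","role":"dropoff","chrom":"chrX","start":1187610,"end":1187630,"cpg":1187618},{"name":"CRLF2_REF","dye":"HEX","role":"reference","chrom":"chrX","start":1187640,"end":1187665,"cpg":[]}],"amplicon":{"chrom":"chrX","start":1187500,"end":1187680}}
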