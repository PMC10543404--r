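{"name":"BCL2_ABC_synthetic","probes":[{"name":"BCL2_FAM","dye":"FAM","role":"dropoff","chrom":"chr18","start":63318042,"end":63318062,"cpg":63318050},{"name":"BCL2_Cy5","dye":"Cy5","role":"dropoff","chrom":"chr18","start":63318087,"end":63318107,"cpg":63318095},{"name":"BCL2_REF","dye":"HEX","role":"reference","chrom":"chr18","start":63318125,"end":63318150,"cpg":[]}],"amplicon":{"chrom":"chr18","start":63318000,"end":63318160}}
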