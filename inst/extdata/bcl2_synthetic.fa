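>BCL2_ABC_synthetic
CTGTTCCAGCTCTAAAGACCATTCTTAGGATGTGTATAATTAAGGATCTACGTGTTTGTCTCACAAATTGGTAGTTACAT
GAATTATGTAGGTTACGTGTCTAAGGTAATGATTCCTACACTGATAATTGCTCTGAATTTATTAAATTGCAAGGTATCTC
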