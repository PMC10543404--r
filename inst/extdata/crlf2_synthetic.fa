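>CRLF2_ABC_synthetic
ATTTATGCTTGAAATTGCTTTTGATGTTTTAGACTATAGGTATTAGATTTCTTAGATACGAAGGAGGTAGTAATCGATAT
TGATGTAGGTCCTTCTCATTGCTTGATAAGAACTTTGACGTTACTTAATGATAGTTGAACCAACCATGCTAGCATACTGA
TTGTTCAGTTGACAGAAAGT
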