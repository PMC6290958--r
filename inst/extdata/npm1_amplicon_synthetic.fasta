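>NPM1_exon12_synthetic synthetic stand-in amplicon for the NPM1 exon-12 target region
CCATGAGTTAACTGTCGAGCAAGCAATCCGCTTGAGCGTACTAACCAGACCGACTTGACA
GAGGGAACGGATCTGGGTATAATACACCTCCCGAGCCTACGACATTGTCTTTCTATCGCA
GTGACCAGCACTGATCCCGTTCTTAGAGACATGTATAGTCGGATATGCCATTGATAGAAT
GTGGCACACTTGGAGTGACGATCACGTGCTACGCACAGATCGTTAGTTGGGCAGTCAGGT
GTAGCCTAGA
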