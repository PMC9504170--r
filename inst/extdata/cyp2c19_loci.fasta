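>rs4244285
CACTATCATTGATTATTTCCCGAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATT
ATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTAT
AATTATAATTATGCTTCCTGATCAAAATGGAG
>rs4986893
GGATTGTAAGCACCCCCTGGAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTAT
AATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAA
TTATAATTATCTGGAAAAGATGGCAAAGTTCT
>rs12248560
GTGTCTTCTGTTCTCAAAGCAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTAT
AATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAATTATAA
TTATAATTATGTCTCCCTTTTCCCATTTG
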