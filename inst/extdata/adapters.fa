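>TruSeq_Universal_Adapter
AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT
>TruSeq_Adapter_Read1
AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC
>TruSeq_Adapter_Read2
AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA
>Nextera_Transposase_1
TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG
>Nextera_Transposase_2
GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG
>Illumina_Small_RNA_3p
TGGAATTCTCGGGTGCCAAGG
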