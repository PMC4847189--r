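>satEC_synthetic_monomer 221 bp synthetic stand-in, GC 117/221
TAGCGCCATTATCTCGGGTCGGTTATCATGGTGCCAAAGGTATATCCCTGAAACTGGTGG
AACGGTCTCACACTTTTTACGTGACGCGCGGGGATAGTAGAGGTCTCCTCTCAGAAAATC
TGGATTTGTCTACTCCGATTCGCCATTGCGGACGCGTTCGCCTAGCTTGAATCGGCCGTT
GCGTAGCAACTCCAGGTGGTCGCTCGGCAGATTGCGATTCA
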