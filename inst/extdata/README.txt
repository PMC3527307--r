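Synthetic example data: 6 haplotypes simulated over 5 kb (theta 0.008/bp,
background rho 0.02/bp with a 1 kb 10x hotspot, 5% missing entries), written
as SNP-allele FASTA plus a 1-based positions file.
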