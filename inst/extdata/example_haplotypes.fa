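>hap1
GTGCCGCCGTTATCACATTGNGCGGCTGCTGTCTTAAAAACTATAATNGTGANGTTAAATCACTTAACTCCACACCCTACTCCGTTCTTACANTCGGCAGCG
>hap2
CGAGAAGGACCTNAGTCGCTTCAGGTGTCGCCATTACAAACGATAGNGCCNCNGTTGAGCCTCGTATCTACACACCCAGGTCCACTNTTACANTCNTCAGAA
>hap3
GTGCCGCCGTTATCACATTGAGCGGCTGCTGTNTTAAAAACTATAATTGTGNTGTTNAATCACTNAACTANACACCCTACTCCGTTATTACTATCGTTAANA
>hap4
CGANAAGGACNTCAGTCGCTTCACATGGCTCCCTNGAAAACTATAATTGTGCCGTTGAATCACTTGTATACNAAGTCANCCTAGTACANACATCCCTCAGCG
>hap5
CTGCCGCNGTTATCACATTGNGCGGCNGCTGTCTTAAAAGTGATTGCGCTTCCGTTGAATTAGGTGTCCAGGCACCTNACCTAGTACAAAGATCTCTCTGCG
>hap6
GTGCCGCCGTTATCACATNNAGCGGCTGGTGTACCACCGACGTCTATTGTGATCGAGTACCTCGCNACCAGNCTCCTTACCTAGTTATATCTTTCGTCAGCA
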