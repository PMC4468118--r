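>psbF_operon_synthetic synthetic analog; psbF CDS 31-150, psbL CDS 230-289, editing site 107, poly-T run 98-106
AATCCGGCCCCCTCCACAAGGATCGGCTCAATGCTTCCTCTTCACCATGCACTCTTATTTAATCTCGATG
AACACGTACACATGGCCGCGAACAACCTTTTTTTTTCTTTTGCAAACCCTGGGCTGTCCCTCAGCGTCAA
CAGGCCTTAATCTACTAATTGAGACATCCTCCTGTGCTGGCTTCACGGTGGATTCTAAAGAATTTCGTAT
TTCCTGCCTGGCAGTTGCGATGCACATAGTATCTCTCCTATCATCGGATTGGTCCCTAGCGCGTGCCTGT
GTGGAGTAATCCCCTCCTATCGCTAGTACAGTGGTGCCGGTCGTGGCCCAACGCTCAGCCCGTTTAAACA
CGTGTGCAT
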