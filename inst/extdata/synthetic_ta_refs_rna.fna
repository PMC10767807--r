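>sok_syn|antitoxin|I|hok-sok
GCACGTGCTGAAAAGTAACTGTCGGGTCTCAGCATTGCCCACAGTAAAATTATTAATGTTTAGCC
>toxI_syn|antitoxin|III|toxIN
AGGCTAGCTGGGCAGACCACGACTTGGCTGTCCGTCTGACTCCAGTGCTAACATGAGGCCACCCCTCTAACTCATTTACACCTATGGCGCAGCGGGGAGCGGAAGCCAAT
>creT_syn|toxin|VIII|creTA
TGAGATCGCAGGTGCGATAAATGGAGGTACCGTCGATAAAAGCGGTTAAAGGACGGGCACGGCACTTCACGTGCCTGCCTCACTTGTAGC
>creA_syn|antitoxin|VIII|creTA
CTCGCGGGCGACTTTAAAGTGCGGTGGTTAAACATCGTTGATCAGTGGACTCCCGAACTAGTAGGATTCTAACGATTCTACGTAAGAGGCTCACACTTGT
>sdsR_syn|toxin|VIII|sdsR-ryeA
GCAGGCGCAGCTATTCGACGTCTGGGGACCGCTCGGGCAACTTTCAACACGATATGGGCCTGGTACACATTTTAGAGATATTTATGGTGCGATGCTAGACATCA
>ryeA_syn|antitoxin|VIII|sdsR-ryeA
CGGGCGGCATAATATTCGGATGCTCGAGAAAGGAACGGGCTTCAGCTAGACCGCGAATAACGTCCACGCCTTACTACTGGAATAATGAAATTGAGTTGGCAGCGGACCGAAACTGATAAC
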