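trinucleotide	weight	background_freq
AAA	1	0.015625
AAC	0	0.015625
AAG	0	0.015625
AAT	1	0.015625
ACA	0	0.015625
ACC	0	0.015625
ACG	0	0.015625
ACT	0	0.015625
AGA	0	0.015625
AGC	0	0.015625
AGG	0	0.015625
AGT	0	0.015625
ATA	1	0.015625
ATC	0	0.015625
ATG	0	0.015625
ATT	1	0.015625
CAA	0	0.015625
CAC	0	0.015625
CAG	0	0.015625
CAT	0	0.015625
CCA	0	0.015625
CCC	0	0.015625
CCG	0	0.015625
CCT	0	0.015625
CGA	0	0.015625
CGC	0	0.015625
CGG	0	0.015625
CGT	0	0.015625
CTA	0	0.015625
CTC	0	0.015625
CTG	0	0.015625
CTT	0	0.015625
GAA	0	0.015625
GAC	0	0.015625
GAG	0	0.015625
GAT	0	0.015625
GCA	0	0.015625
GCC	0	0.015625
GCG	0	0.015625
GCT	0	0.015625
GGA	0	0.015625
GGC	0	0.015625
GGG	0	0.015625
GGT	0	0.015625
GTA	0	0.015625
GTC	0	0.015625
GTG	0	0.015625
GTT	0	0.015625
TAA	1	0.015625
TAC	0	0.015625
TAG	0	0.015625
TAT	1	0.015625
TCA	0	0.015625
TCC	0	0.015625
TCG	0	0.015625
TCT	0	0.015625
TGA	0	0.015625
TGC	0	0.015625
TGG	0	0.015625
TGT	0	0.015625
TTA	1	0.015625
TTC	0	0.015625
TTG	0	0.015625
TTT	1	0.015625
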