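#name=nucleosome_preference
#unit=arbitrary units
#source=synthetic stand-in scale; values are NOT the published parameters, only qualitatively calibrated (see package documentation)
AAA	-0.5878
AAC	-0.0379
AAG	0.0047
AAT	-0.5809
ACA	-0.1147
ACC	0.0732
ACG	0.1387
ACT	-0.0784
AGA	-0.1428
AGC	0.1361
AGG	0.0372
AGT	0.0434
ATA	-0.7356
ATC	-0.0011
ATG	-0.0245
ATT	-0.5777
CAA	-0.0222
CAC	0.0816
CAG	0.1420
CAT	0.0660
CCA	0.1062
CCC	0.2560
CCG	0.2784
CCT	0.0617
CGA	0.1043
CGC	0.2751
CGG	0.2945
CGT	0.1086
CTA	0.0166
CTC	0.0492
CTG	0.0941
CTT	-0.1212
GAA	-0.0928
GAC	0.1081
GAG	0.1458
GAT	-0.0200
GCA	0.1080
GCC	0.2032
GCG	0.1776
GCT	0.1490
GGA	0.1593
GGC	0.1878
GGG	0.2281
GGT	0.1798
GTA	-0.0761
GTC	0.1334
GTG	-0.0065
GTT	-0.1477
TAA	-0.6098
TAC	-0.1045
TAG	-0.0366
TAT	-0.6606
TCA	-0.0065
TCC	0.0820
TCG	0.1443
TCT	0.0159
TGA	0.0418
TGC	0.0602
TGG	0.1021
TGT	-0.0705
TTA	-0.6909
TTC	0.0615
TTG	0.0242
TTT	-0.6798
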