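#name=bendability
#unit=arbitrary units
#source=synthetic stand-in scale; values are NOT the published parameters, only qualitatively calibrated (see package documentation)
AAA	-2.0807
AAC	1.3465
AAG	1.4023
AAT	-2.5756
ACA	1.5641
ACC	3.2600
ACG	2.9371
ACT	1.9457
AGA	1.6499
AGC	2.5017
AGG	3.1417
AGT	1.1020
ATA	-2.4051
ATC	1.4069
ATG	1.4813
ATT	-2.6736
CAA	1.4342
CAC	2.7378
CAG	3.1692
CAT	1.5052
CCA	3.2789
CCC	3.9009
CCG	4.1594
CCT	3.4984
CGA	2.3499
CGC	4.6842
CGG	3.9912
CGT	2.6896
CTA	1.2567
CTC	3.0233
CTG	2.8784
CTT	0.6121
GAA	1.4633
GAC	2.7222
GAG	3.1800
GAT	1.0229
GCA	2.9944
GCC	4.0860
GCG	4.6149
GCT	2.8593
GGA	3.2524
GGC	4.3057
GGG	4.2767
GGT	3.1374
GTA	0.6445
GTC	3.0628
GTG	3.4317
GTT	1.4246
TAA	-1.9793
TAC	1.1656
TAG	1.0415
TAT	-2.7989
TCA	1.5188
TCC	3.5085
TCG	3.0179
TCT	1.6438
TGA	2.0113
TGC	2.9767
TGG	3.4331
TGT	1.5795
TTA	-2.1524
TTC	1.6280
TTG	2.0709
TTT	-2.6016
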