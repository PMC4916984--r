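#name=deformability
#unit=arbitrary units
#source=synthetic stand-in scale; values are NOT the published parameters, only qualitatively calibrated (see package documentation)
AA	2.1799
AC	1.6266
AG	2.7853
AT	1.3752
CA	5.1030
CC	3.0245
CG	4.8441
CT	2.7603
GA	2.8713
GC	1.4831
GG	2.8292
GT	1.9709
TA	4.6278
TC	2.9746
TG	5.2038
TT	2.3479
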