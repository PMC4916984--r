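#name=stiffness
#unit=arbitrary units
#source=synthetic stand-in scale; values are NOT the published parameters, only qualitatively calibrated (see package documentation)
AA	6.9802
AC	7.6199
AG	6.1529
AT	7.4358
CA	3.6738
CC	5.8345
CG	4.3545
CT	6.2985
GA	6.5497
GC	7.9010
GG	6.2794
GT	6.8562
TA	4.4554
TC	6.1554
TG	3.8252
TT	6.4154
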