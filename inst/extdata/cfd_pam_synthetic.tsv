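# Synthetic CFD-style PAM penalty table keyed on the last two PAM bases.
# NOT the published CFD values; canonical NGG suffix GG = 1.0.
# provenance: synthetic, motifguides package
pam_suffix	penalty
AA	0.01
CA	0.01
GA	0.07
TA	0.01
AC	0.01
CC	0.01
GC	0.02
TC	0.01
AG	0.26
CG	0.03
GG	1.00
TG	0.04
AT	0.01
CT	0.01
GT	0.05
TT	0.01
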