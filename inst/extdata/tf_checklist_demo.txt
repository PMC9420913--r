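# Small demonstration TF checklist (DNA-binding RNA-polymerase-II TFs).
# A real analysis should use a full curated checklist export
# (one symbol per line); this subset covers common neurodevelopmental TFs.
RUNX1T1
SOX5
FOXP1
MEF2C
TCF4
EYA2
RORB
LHX9
LEF1
SATB2
BCL11B
EMX1
EOMES
PAX6
NEUROD1
NEUROD4
SOX2
DLX1
DLX5
ARX
HES1
OLIG1
NR2F1
NR2F2
LHX6
SOX6
FEZF2
CUX2
TBR1
OTX2
PAX3
DBX1
FOXG1
NGN2
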