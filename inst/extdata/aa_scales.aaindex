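H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.800  -4.500  -3.500  -3.500   2.500  -3.500  -3.500  -0.400  -3.200   4.500
    3.800  -3.900   1.900   2.800  -1.600  -0.800  -0.700  -0.900  -1.300   4.200
//
H SYNLNK0001
D Synthetic linker propensity index (constructed placeholder encoding
D enrichment of small/polar residues and depletion of hydrophobics in
D inter-domain linkers; not a published scale)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.000   0.950   1.100   1.050   0.700   1.150   1.100   1.200   0.950   0.750
    0.800   1.000   0.800   0.700   1.400   1.300   1.100   0.600   0.750   0.800
//
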