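protein,peptide,mods,declared_mods,z,expected_mz,rt_min
TUBB3,ISVYYNEASSHK,,,3,466.561,22
TUBB3,LHFFMPGFAPLTSR,,oxidation@5,2,810.921,76
GFAP,ALAAELNQLR,,,2,549.817,45
GFAP,LEVERDNLAQDLATVR,,,3,614.663,54
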