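# Solvent and common crystallisation-additive het codes removed by
# strip_solvent() by default. Edit freely; metals are not listed because
# they can be functional cofactors.
HOH
DOD
GOL
EDO
PEG
SO4
PO4
CL
NA
K
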