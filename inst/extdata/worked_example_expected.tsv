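metabolite	consumption
ATP	10
CTP	11
Dol-P-Glc	33
Dol-P-Man	52
FADH2	1
GDP-Man	144
GPI-anchor	1
GTP	28
LLO	11
O2	1
PE	3
PI	1
UDP-Glc	44
UDP-GlcNAc	23
acyl-CoA	2
farnesyl-PP	11
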