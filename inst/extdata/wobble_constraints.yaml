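# Selective constraints S_ij for non-Watson-Crick codon:anticodon pairing
# geometries, as used by the reference tAI parameterization (dos Reis et al.
# 2004). Watson-Crick pairings always carry S = 0 and are not listed.
#   G:U  codon ending T read by a G34 anticodon
#   I:C  codon ending C read by an A34 (inosine) anticodon
#   I:A  codon ending A read by an A34 (inosine) anticodon
#   U:G  codon ending G read by a T34 anticodon
#   L:A  prokaryotic ATA read by the lysidine-modified CAT anticodon
"G:U": 0.41
"I:C": 0.28
"I:A": 0.9999
"U:G": 0.68
"L:A": 0.89
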