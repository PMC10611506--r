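# Basic-property categories of the 20 standard amino acids, by polarity and
# charge, at the five-subcategory level used for impact scoring.
residue	category
Ala	nonpolar_aliphatic
Arg	basic
Asn	polar_uncharged
Asp	acidic
Cys	polar_uncharged
Gln	polar_uncharged
Glu	acidic
Gly	nonpolar_aliphatic
His	basic
Ile	nonpolar_aliphatic
Leu	nonpolar_aliphatic
Lys	basic
Met	nonpolar_aliphatic
Phe	nonpolar_aromatic
Pro	nonpolar_aliphatic
Ser	polar_uncharged
Thr	polar_uncharged
Trp	nonpolar_aromatic
Tyr	nonpolar_aromatic
Val	nonpolar_aliphatic
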