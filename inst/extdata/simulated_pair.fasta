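>lineage1 t=0.2 seed=42 S=0,0,8,8
AATAAAATAATAAATAAATAATAATATATAAATATATAAATTTTTATAATTTTATTATAA
AAAAATTATTTAAATATTATATTAAATTTTATTAAAAAAAATTTAAAAATAAAAAATAAA
TTAATTTATATTAATTATATTTTTAATATTATATATTTTTAAATATTTTTATATTAAAAT
AATTAAATTTTATTTTATAAAAATTTATTTAATATTATTATTAATAATTTTTTTAATAAT
TATTATTTTATATATATTAAATTAATTTAATATTATTTTTTTTATATTTTATAATAAATT
>lineage2 t=0.2 seed=42 S=0,0,8,8
AATAAAATAATAAATAATTAATAATATTTTTAATTATAAATTTAAAAAATTTTTTAATTA
TAAAATAATTTATATATAATATTATTTAATATTAAATATAATTTAAAAATAAATAATTAA
ATAAAAAATAAAAAATATAATTTTAAAATTAAAAAATATAAATTATTTTTATTTTTAAAA
AATTAAAATTTATTTTATATAAATATTTTTAATATTATTATTAAAATTTTTTTTAATAAT
TATAATTTTATTTATAAAAAAATAATATTATATTATTTTTTTTATTTTTTATTTTTAATT
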