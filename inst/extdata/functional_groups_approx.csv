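group,smarts,note
phenols,c1ccccc1[OX2H],approximate generic pattern
thiophosphoric acid derivatives,P(=S),approximate generic pattern
nitro compounds,[NX3](=O)=O,approximate generic pattern
diarylethers,c[OX2]c,approximate generic pattern
benzyl halides,"c[CH2][F,Cl,Br,I]",approximate generic pattern
gem-trihalides,"C([F,Cl,Br,I])([F,Cl,Br,I])[F,Cl,Br,I]",approximate generic pattern
primary aromatic amines,c[NX3H2],approximate generic pattern
aryl halides,"c[F,Cl,Br,I]",approximate generic pattern
arenes,c1ccccc1,approximate generic pattern
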