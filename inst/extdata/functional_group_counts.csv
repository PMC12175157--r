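group,n_active_with,n_inactive_with
phenols,157,9
thiophosphoric acid derivatives,29,3
nitro compounds,56,7
diarylethers,40,5
benzyl halides,42,7
gem-trihalides,72,13
primary aromatic amines,53,11
aryl halides,185,50
arenes,609,168
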