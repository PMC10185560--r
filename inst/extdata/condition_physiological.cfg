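# Profiling convention: transformed energies at pH 7.5, I = 0.20 M, 298.15 K,
# reactants at 1 mM unless stated.
ph = 7.5
ionic_strength = 0.20
temperature = 298.15
default_conc = 0.001
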