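# Example simulation configuration: a structured culture with a fold-2
# over-secreting mutant. Unset keys take the package defaults.
mixing: 0
mutant_secretion_fold: 2
n_transfers: 25
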