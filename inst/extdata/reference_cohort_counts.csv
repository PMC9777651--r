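quantity,value
cohort_n_baseline,114516
cohort_n_end,72091
n_died,39365
n_polypharmacy_baseline,95588
n_polypharmacy_end,62716
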