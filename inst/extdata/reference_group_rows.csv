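pattern,group,wave,prevalence_pct,oe_ratio,exclusivity_printed_pct,cluster_n,population_n
mental_behavioural_digestive_cerebrovascular,dementia,baseline,48.96,8.67,67.69,8937,114516
multisystemic,chronic_pancreas_biliary_gallbladder,baseline,27.74,7.24,37.50,5929,114516
mental_behavioural_digestive_cerebrovascular,dementia,end,57.70,8.02,52.95,4757,72091
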