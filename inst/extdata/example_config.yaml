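# Example cohort configuration: observational disease preset with the
# calibrated post-onset CFHR1 shift, 1% genotype missingness.
disease_preset: observational
onset: cfhr1
missing_rate: 0.01
prevalence: 0.10
n_population: 1004
n_replication: 500
n_cases_bio: 382
n_controls_bio: 201
n_advanced_bio: 242
n_cases_geno: 874
n_controls_geno: 418
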