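# Staged spikelet expression scenario: 5,000 genes (4,900 expressed),
# WT/mutant x {S1-whole, S3-whole, S4-PS, S4-SS, S5-PS, S5-SS} with 3
# replicates (each emulating a 10-plant pool, hence low replicate
# noise), 167 planted pattern genes. log2 noise sd 0.08 puts the
# planted 4-log2-unit rule margins at ~60 sd of a condition mean and
# makes 3-replicate Welch significance essentially certain; see the
# methods vignette for the calibration.
seed: 1
n_expressed_genes: 4900
n_unexpressed_genes: 100
n_target_genes: 167
n_replicates: 3
noise_sd: 0.08
peak_log2fc: 4
go_n_null_terms: 12
go_null_size_range: [20, 200]
go_enriched:
  term_id: ["GO:SIM0001", "GO:SIM0002", "GO:SIM0003"]
  n_targets: [12, 9, 7]
  n_background: [40, 66, 61]
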