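# Bulk-segregant mapping scenario: 2 x 500 kb genome, 120 genes,
# 17 independent EMS lines (7 allelic at the causal gene), a 50-plant
# selected F2 bulk at mean depth 27 with a 14-variant planted pass set
# and 50 decoys per violated filter predicate.
seed: 1
n_chromosomes: 2
chromosome_length: 500000
n_genes: 120
mean_exons_per_gene: 3
gc_fraction: 0.44
mutations_per_line: 25
n_mutant_lines: 17
n_allelic_lines: 7
bulk_size: 50
bulk_coverage: 27
line_coverage: 20
linked_window: 100000
n_bulk_mutations: 14
n_parent_sites: 150
decoys_per_filter: 50
line_decoys_per_filter: 5
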