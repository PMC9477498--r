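# Demo pipeline configuration: reduced resampling counts for a quick
# end-to-end run on a generated fixture. Unset keys take the package
# defaults (192/23 cutoffs, bin size 10, 5000/1000/500 permutations and
# bootstraps, 100 repetitions with the >90 rule, fivefold CV).
seed: 5
sim:
  n_per_cell: 10
seeds:
  n_perm: 500
pls:
  n_perm: 199
  n_boot: 50
groupstats:
  n_perm: 499
svc:
  n_rep: 10
  threshold: 9
  n_lambda: 10
  pathology_groups: ["A+"]
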