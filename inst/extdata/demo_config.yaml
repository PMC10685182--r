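# Demo pipeline configuration: two simulated subpopulations (cognate
# cohort 333 M / 88 F; non-cognate reference of 2793 individuals) diverged
# at F = 0.01, analysed end to end.
seed: 7
output_dir: strpop_out
simulate:
  f: 0.01
cohort: QiangLike
reference: HanLike
hwe:
  dememorization: 20000
  steps: 200000
ld:
  pairs:
    - [DXS10079, DXS6800]
  sex: M
  n_perm: 1000
fst:
  n_perm: 1000
audit:
  f_list: [0, 0.0016, 0.0108, 0.0170]
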