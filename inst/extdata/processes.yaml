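# Default process definitions for the roll-up table. A process is scored by
# the maximum hit count over its member genes (any single subunit evidences
# the system); hydrogenase classes are sums over their group profiles.
# Which genes define a process is an analysis choice with direct impact on
# the results -- edit freely and pass the file to run_annotate().
Methanotrophy:
  genes: [pmoA, pmoB, pmoC]
  roll_up: max
Nitrate reduction:
  genes: [narG]
  roll_up: max
Nitrite reduction:
  genes: [nirK]
  roll_up: max
Sulfite reduction:
  genes: [dsrA]
  roll_up: max
FeFe hydrogenases:
  genes: [FeFe-A]
  roll_up: sum
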