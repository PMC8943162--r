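# Example configuration for the `mi` subcommand of inst/cli/channelmi.R.
# Paths are relative to the working directory the CLI is invoked from.
topology: sim/trajectory.pdb
runs:
  run1: [sim/trajectory.pdb]
monomers: [A, B, C, D]
segments:
  - {name: lid,  first: 663, last: 676}
  - {name: S1,   first: 706, last: 730}
  - {name: S4,   first: 842, last: 865}
  - {name: TRPL, first: 961, last: 1005}
mi:
  fit_segment: TRPL
  eigenvalue_floor: 1.0e-8
  top_k: 25
  min_value: 0
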