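# Example configuration for the gliovasc CLI.
#   gliovasc simulate --config example-sweep.yaml --out run/
#   gliovasc sweep    --config example-sweep.yaml --out maps/
# Any omitted parameter takes the package default (physiological baseline).
variant: III
nx: 2001
output_every: 10
params:
  D: 0.0273        # intrinsic diffusion, mm^2/day
  b: 0.00273       # intrinsic proliferation, 1/day
  h2: 5.73e-3      # oxygen consumption, mm/(cell day)
  g2: 5.0e-13      # vaso-occlusion rate, cell^-n mm^n / day
sweep:             # used by the `sweep` subcommand
  D_values: [2.73e-3, 1.723e-2, 1.087e-1, 2.73e-1]
  b_values: [2.73e-4, 1.723e-3, 1.087e-2, 2.73e-2]
  varied_name: g2
  varied_values: [5.0e-13, 1.5e-11]
  L: 300
  T_f: 1000
  dx: 0.25
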