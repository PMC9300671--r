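# Example bipsim run configuration (desk-scale mixed-phase point).
# Usage: bipsim simulate example_run.toml --out demo

[system]
N = 64          # protein dimers
L = 64          # polymer beads
lx = 14.0       # box edge (sigma)
boundary = "walls"
seed = 1

[forcefield]
variant = "multivalent"
eps_hh = 2.0    # hinge-NTE attraction (kT)
eps_hc = 2.0    # CD-bead attraction (kT)

[dynamics]
dt = 0.001
gamma = 1.0
skin = 0.3

[protocol]
run_tau = 20
equil_frac = 0.5
seeds = [1, 2]
sample_tau = 2
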