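{
  "config": {
    "n_molecules": 200,
    "box_length": 36,
    "timestep": 0.005,
    "langevin_damping": 1,
    "temperature": 1,
    "n_steps": 10000,
    "seed": 7,
    "snapshot_interval": 500
  },
  "force_field": {
    "eps_H": 0.05,
    "eps_E": 5,
    "screening_length": 1,
    "r_cut": 2,
    "exclusion_depth": 5
  },
  "template": {
    "n_beads": 36,
    "bead_diameter": 1.12,
    "bond_r0": 0.255,
    "bond_k": 500,
    "angle_theta0": 3.141592653589793,
    "angle_k": 50,
    "charges": [0, 1, 0, 0, 1, 0, 0, 1, 0, 0, 1, 0,
                0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                -1, 0, 0, -1, 0, 0, -1, 0, 0, -1, 0, 0]
  }
}
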