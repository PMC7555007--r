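# Example configuration for synapsim / synapse-abm.
# Any omitted field falls back to the package default.
lattice:
  nodes_per_side: 89
  node_spacing: 0.081      # um per node
  synapse_radius: 3.5      # um
  tau: 0.01                # s
  membrane_gap_height: 0.015  # um; V = spacing^2 * gap
species:
  TCR:   {density: 18,  D: 0.05}   # molecules/um^2, um^2/s
  pMHC:  {density: 30,  D: 0.11}
  LFA1:  {density: 50,  D: 0.05}
  ICAM1: {density: 50,  D: 0.11}
rules:
  "TCR:pMHC":   {kon: 2.0e5, koff: 0.1}    # 1/(M s), 1/s
  "LFA1:ICAM1": {kon: 2.0e5, koff: 0.03}
forces:
  R_force: 0.5             # um
  sbs_strength: 0.4
  centripetal_strength: 0.3
  centripetal_strength_adhesion: 0.03
  coupling_enabled: true
foci:
  enabled: false
  R_neighborhood: 0.35     # um
  p_nucleate: 0.1
  p_nuc_polymerize: 0.1
  p_polymerize: 0.05
  p_decay: 0.01
  B: 1.0
B_global: 1.0
seed: 1
duration: 600              # s
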