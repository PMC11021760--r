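# Default medicinal-chemistry filter (MCF) rule set.
#
# This list is this package's own, fully documented rule set (reactive or
# unstable groups plus basic composition limits); replace it wholesale by
# passing load_filter_rules("my_rules.yaml") to apply_mcf(). Structural
# alerts are SMARTS; terminal alerts additionally run (enhanced mode only)
# against acyclic peripheral substituents. Note that carbonyl-hydration
# liability (geminal diols) is included here as an alert even though some
# generators tolerate it.

alerts:
  - {name: acyl_halide,        smarts: "[CX3](=O)[F,Cl,Br]",    severity: reject}
  - {name: peroxide,           smarts: "[OX2][OX2]",            severity: reject}
  - {name: geminal_diol,       smarts: "[CX4]([OX2H1])[OX2H1]", severity: reject}
  - {name: aliphatic_aldehyde, smarts: "[CX3H1]=O",             severity: reject}
  - {name: azo_chain,          smarts: "N=N",                   severity: reject}
  - {name: michael_extreme,    smarts: "[CX3H2]=[CX3]C=O",      severity: reject}
  - {name: isocyanate,         smarts: "N=C=O",                 severity: reject}
  - {name: hemiaminal,         smarts: "[CX4]([OX2H1])[NX3]",   severity: reject}

terminal_alerts:
  - {name: terminal_aldehyde,   smarts: "[CX3H1]=O",          severity: reject}
  - {name: terminal_acyl_halide, smarts: "[CX3](=O)[F,Cl,Br]", severity: reject}
  - {name: terminal_peroxide,   smarts: "[OX2][OX2]",         severity: reject}

allowed_elements: ["C", "H", "N", "O", "S", "F", "Cl", "Br"]

ring_size: {min: 3, max: 8}

# property bounds (enhanced mode only); omit or null = unbounded
properties:
  mw_max: 550
  heavy_atoms_max: 40
  rotatable_bonds_max: 10
  ring_count_max: 6
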