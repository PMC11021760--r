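# Hotspot typing table: which protein atoms count as hydrogen-bond donors,
# acceptors, aromatic ring systems and apolar (hydrophobic) carbons.
# This table is this package's own typing convention; edit or replace it via
# detect_hotspots(rules = load_hotspot_rules("my_rules.yaml")).
#
# "backbone" entries apply to every residue. Side-chain entries are keyed by
# three-letter residue name. Amide nitrogens of Asn/Gln side chains are
# donors only; pyridine-type ring nitrogens (His ND1 when unprotonated) are
# acceptors; quaternary/amide nitrogens are never acceptors.

donors:
  backbone: ["N"]
  SER: ["OG"]
  THR: ["OG1"]
  TYR: ["OH"]
  CYS: ["SG"]
  LYS: ["NZ"]
  ARG: ["NE", "NH1", "NH2"]
  TRP: ["NE1"]
  HIS: ["NE2"]
  ASN: ["ND2"]
  GLN: ["NE2"]

acceptors:
  backbone: ["O", "OXT"]
  SER: ["OG"]
  THR: ["OG1"]
  TYR: ["OH"]
  ASP: ["OD1", "OD2"]
  GLU: ["OE1", "OE2"]
  ASN: ["OD1"]
  GLN: ["OE1"]
  HIS: ["ND1"]

aromatic_rings:
  PHE: ["CG", "CD1", "CD2", "CE1", "CE2", "CZ"]
  TYR: ["CG", "CD1", "CD2", "CE1", "CE2", "CZ"]
  TRP: ["CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"]
  HIS: ["CG", "ND1", "CD2", "CE1", "NE2"]

hydrophobic:
  # apolar carbon = carbon with no N/O/S within covalent range; a hotspot is
  # the centroid of >= min_atoms apolar carbons that are mutually within
  # cluster_distance angstroms
  min_atoms: 3
  cluster_distance: 5.0
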