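# Physical constants for the commercial lipid species used in the mimic
# formulations. Molar masses are supplier-catalog values (Sigma-Aldrich for
# cholesterol, Avanti Polar Lipids for the phospholipids); reference
# per-molecule leaflet areas are typical fluid-phase literature values and
# are only used when the per-species area mode is selected (the default
# budget model uses a single uniform effective area).
species:
  Chol:
    name: Cholesterol
    family: Chol
    molar_mass: 386.7        # g/mol, Sigma C8667
    ref_area: 0.40           # nm^2, condensed sterol area
  SM:
    name: "16:0 SM (d18:1/16:0)"
    family: SM
    molar_mass: 703.0        # g/mol, Avanti 860584
    ref_area: 0.55
  DSPE-PEG2000:
    name: "DSPE-PEG(2000) Amine"
    family: PE
    molar_mass: 2790.0       # g/mol, Avanti 880128 (polymer-average)
    ref_area: 0.70
  18:2 PE:
    name: "18:2 PE (dilinoleoyl)"
    family: PE
    molar_mass: 738.0        # g/mol, Avanti 850755
    ref_area: 0.65
  DOPC:
    name: "DOPC (18:1 PC)"
    family: PC
    molar_mass: 786.1        # g/mol, Avanti 850375
    ref_area: 0.72
  16:0 PS:
    name: "16:0 PS (sodium salt)"
    family: PS
    molar_mass: 758.0        # g/mol, Avanti 840037
    ref_area: 0.55
  18:1 PA:
    name: "18:1 PA (sodium salt)"
    family: PA
    molar_mass: 723.0        # g/mol, Avanti 840875
    ref_area: 0.60
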