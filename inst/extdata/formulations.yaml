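# Artificial lipidic compositions mimicking PC3-derived EVs, as mass
# percentages per commercial species. The cholesterol-enriched (CE) variants
# raise cholesterol to 30% and rebalance the remaining species
# proportionally. Species keys refer to inst/extdata/lipid_catalog.yaml.
mimic-1:
  label: "Mimic 1"
  mass_fraction:
    Chol: 13.0
    SM: 20.0
    DSPE-PEG2000: 16.0
    DOPC: 26.0
    18:1 PA: 25.0
mimic-2:
  label: "Mimic 2"
  mass_fraction:
    Chol: 13.0
    SM: 20.0
    DSPE-PEG2000: 16.0
    DOPC: 26.0
    16:0 PS: 25.0
mimic-3:
  label: "Mimic 3"
  mass_fraction:
    Chol: 13.0
    SM: 20.0
    DSPE-PEG2000: 10.0
    18:2 PE: 6.0
    DOPC: 26.0
    16:0 PS: 25.0
ce-mimic-1:
  label: "CE Mimic 1"
  mass_fraction:
    Chol: 30.0
    SM: 16.1
    DSPE-PEG2000: 12.9
    DOPC: 20.9
    18:1 PA: 20.1
ce-mimic-2:
  label: "CE Mimic 2"
  mass_fraction:
    Chol: 30.0
    SM: 16.1
    DSPE-PEG2000: 12.9
    DOPC: 20.9
    16:0 PS: 20.1
ce-mimic-3:
  label: "CE Mimic 3"
  mass_fraction:
    Chol: 30.0
    SM: 16.1
    DSPE-PEG2000: 8.0
    18:2 PE: 4.8
    DOPC: 20.9
    16:0 PS: 20.1
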