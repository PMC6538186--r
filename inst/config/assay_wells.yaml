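# Default assay-well geometry by plate footprint (vendor-specification
# class values) and default serum / cell composition for the in vitro
# disposition model. Volumes in uL, areas in mm^2.
geometry:
  "96":   {media_volume: 100, well_area: 32.0,  total_volume: 360}
  "384":  {media_volume: 40,  well_area: 11.0,  total_volume: 112}
  "1536": {media_volume: 8,   well_area: 2.5,   total_volume: 12.5}
# Fetal bovine serum composition (volume fractions of the serum itself)
# and default serum supplementation of the medium.
fbs_fraction: 0.10
serum_lipid_frac: 0.002
serum_protein_frac: 0.030
# Cell composition (volume fractions of total cell volume) and default
# cell load. cell_volume_per_cell in pL.
cell_count: 1.0e+5
cell_volume_per_cell: 2.0
cell_storage_lipid_frac: 0.02
cell_membrane_lipid_frac: 0.03
cell_protein_frac: 0.20
cell_water_frac: 0.70
# Phase-partition QSPR coefficients (log10 K = a * logP + b against the
# aqueous phase). Membrane lipid follows a membrane-water relation,
# serum protein an albumin-binding relation; cell protein is scaled
# albumin-like binding. Plastic sorption is area-based:
# log10 Kplastic (m) = a * logP + b. Only the neutral species partitions
# out of the aqueous phase (switchable).
relations:
  storage_lipid:  {a: 1.00, b: 0.00}
  membrane_lipid: {a: 1.01, b: 0.12}
  serum_protein:  {a: 0.71, b: 0.42}
  cell_protein_scale: 0.05
  plastic:        {a: 0.97, b: -6.94}
  temperature_K: 310.15
  ions_partition: false
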