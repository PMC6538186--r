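# Default rat physiology for the PBTK model (0.25 kg reference animal).
# Flows are PLASMA flows in L/h/kg body weight; volumes in L/kg.
# Values are rounded literature-class constants for an adult rat and are
# deliberately kept in config rather than code so they can be audited and
# swapped.
body_weight: 0.25
plasma_flows:
  cardiac_output: 3.70   # total plasma flow through the lung
  gut: 0.52              # portal inflow to the liver
  liver: 0.08            # hepatic artery
  kidney: 0.52
  rest: 2.58             # balance; gut+liver+kidney+rest == cardiac_output
tissue_volumes:
  gut: 0.027
  liver: 0.034
  kidney: 0.0073
  lung: 0.005
  rest: 0.77
plasma_volume:
  arterial: 0.0105
  venous: 0.0207
gfr: 0.312               # glomerular filtration rate, L/h/kg (plasma)
hepatocellularity: 110   # 10^6 cells per g liver
liver_mass_frac: 34      # g liver per kg body weight
k_gutabs: 2.0            # first-order oral absorption rate, 1/h
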