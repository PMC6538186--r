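# Fractional tissue composition used by the default partition-coefficient
# scheme: water, neutral lipid, phospholipid, and protein volume fractions
# per tissue. Values are rounded rat literature-class numbers; the scheme
# itself is pluggable.
gut:    {water: 0.72, neutral_lipid: 0.049, phospholipid: 0.017, protein: 0.15}
liver:  {water: 0.70, neutral_lipid: 0.035, phospholipid: 0.025, protein: 0.20}
kidney: {water: 0.78, neutral_lipid: 0.021, phospholipid: 0.016, protein: 0.17}
lung:   {water: 0.79, neutral_lipid: 0.008, phospholipid: 0.009, protein: 0.16}
rest:   {water: 0.65, neutral_lipid: 0.100, phospholipid: 0.010, protein: 0.18}
# Plasma protein volume fraction: used to translate plasma binding (fup)
# into a tissue-protein association constant.
plasma: {water: 0.93, neutral_lipid: 0.0, phospholipid: 0.0, protein: 0.074}
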