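# Worked-example reference tables for the egg risk workflow.
#
# These are illustrative, USEPA-style values for demonstration and testing:
# body weights follow Chinese adult/preschool reference values, the intake
# rate corresponds to one egg (50 g) per person per day, and RfD / slope
# factors are the values commonly used in dietary trace-element risk
# assessments. Replace them with the parameters of your own study.
#
# Units: BW kg; FIR g/person/day; EF days/year; ED years; AT days;
# rfd mg/kg/day; sf (mg/kg/day)^-1; limit mg/kg.

basis: dry

exposure_profiles:
  - {group: male,   BW: 65.0, FIR: 50, EF: 365, ED: 70, AT: 25550}
  - {group: female, BW: 56.8, FIR: 50, EF: 365, ED: 70, AT: 25550}
  - {group: child,  BW: 16.2, FIR: 50, EF: 365, ED: 6,  AT: 2190}

toxicity:
  - {metal: Cr, rfd: 0.003,  sf: 0.5}
  - {metal: Mn, rfd: 0.14}
  - {metal: Co, rfd: 0.0003}
  - {metal: Ni, rfd: 0.02}
  - {metal: Cu, rfd: 0.04}
  - {metal: Zn, rfd: 0.3}
  - {metal: As, rfd: 0.0003}
  - {metal: Se, rfd: 0.005}
  - {metal: Cd, rfd: 0.001,  sf: 6.1}
  - {metal: Pb, rfd: 0.0035, sf: 0.0085}

limits:
  - {metal: Pb, authority: GB2762,  limit: 0.2}
  - {metal: Cd, authority: GB2762,  limit: 0.05}
  - {metal: As, authority: GB2762,  limit: 0.5}
  - {metal: Cr, authority: GB2762,  limit: 1.0}
  - {metal: Pb, authority: FAO_WHO, limit: 0.1}
  - {metal: Cd, authority: FAO_WHO, limit: 0.05}
  - {metal: Pb, authority: EC,      limit: 0.1}
  - {metal: Cd, authority: EC,      limit: 0.05}
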