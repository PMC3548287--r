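# Example dehprecon configuration (see read_config()).
# Omitted keys fall back to package defaults; unknown keys are rejected.
#
# Kinetic constants: MEHP's molar excretion fraction (0.059) and 5-hr
# half-life are the calibrated values; the MEHHP/MEOHP/MECPP entries are
# reference literature values from the single-subject self-dosing
# experimental tradition, transcribed here rather than hard-wired in code.
metabolites:
  MEHP:
    f: 0.059
    half_life_hr: 5
    k_a_per_hr: 1.2
    g: 0          # second-phase fraction; 0 = off
    tau_hr: 24    # second-phase lag, hours
  MEHHP:
    f: 0.149
    half_life_hr: 10
  MEOHP:
    f: 0.109
    half_life_hr: 10
  MECPP:
    f: 0.132
    half_life_hr: 12
grid_min: 15
seed: 1
fit:
  prune_threshold: 1      # µg/kg; stepwise-exclusion cut for small events
  rise_increment: 5       # µg/L rise opening a candidate window
  rise_fold: 1.2
  lookahead_hr: 24
  weights:                # loss weights; MEHP down-weighted
    MEHP: 0.25
    MEHHP: 1
    MEOHP: 1
    MECPP: 1
  lod:                    # µg/L; "<LOD" cells imputed at LOD/sqrt(2)
    MEHP: 0.5
    MEHHP: 0.5
    MEOHP: 0.5
    MECPP: 0.5
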