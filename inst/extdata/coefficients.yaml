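# Editable coefficient tables for trophicflux.
#
# PROVENANCE: the values below are PLACEHOLDERS in plausible literature
# ranges, intended for exploratory runs and as a template for users to
# substitute their own published regressions.  None of the package's
# correctness tests depend on these numbers; replace them with
# taxon-specific published coefficients before drawing quantitative
# conclusions from real data.
#
# Load with read_config() companions or yaml::read_yaml(), then pass the
# `metabolic` block as `metabolic_coefficients` to fw_config(), and the
# `allometry` block as `coeffs` to length_to_mass().

# Individual metabolic rate (J h^-1):
#   ln(rate) = ln_b0 + a * ln(mass_mg) - E / (k * T_K)
# with k = 8.617e-5 eV K^-1.  Keys match the `phylo_group` trait column;
# unknown groups fall back to `default`.
metabolic:
  default:     {ln_b0: 23.0, a: 0.70, E: 0.69}
  insect:      {ln_b0: 22.2, a: 0.76, E: 0.67}
  arachnid:    {ln_b0: 22.0, a: 0.57, E: 0.65}
  myriapod:    {ln_b0: 22.8, a: 0.60, E: 0.69}
  crustacean:  {ln_b0: 21.0, a: 0.72, E: 0.63}
  oligochaete: {ln_b0: 23.0, a: 0.80, E: 0.69}
  nematode:    {ln_b0: 23.5, a: 0.84, E: 0.73}

# Length-to-fresh-mass power regressions on the log10 scale:
#   log10(mass_mg) = a_len + b_len * log10(length_mm)
allometry:
  default:     {a_len: -1.10, b_len: 2.90}
  springtail:  {a_len: -1.54, b_len: 2.60}
  mite:        {a_len: -1.35, b_len: 2.65}
  beetle:      {a_len: -0.85, b_len: 2.84}
  spider:      {a_len: -1.00, b_len: 2.74}
  millipede:   {a_len: -1.20, b_len: 2.95}
  earthworm:   {a_len: -1.30, b_len: 2.50}

# Assimilation efficiencies by resource (fractions).  These mirror the
# fw_config() defaults and are repeated here so a single file can carry a
# complete parameterisation for a study.
efficiencies:
  resources: {A: 0.36, P: 0.21, B: 0.96, F: 0.36, L: 0.18, W: 0.18, S: 0.13}
  animal_prey:
    bounds: [0.50, 0.99]    # linear in prey body N% over N_range
    N_range: [5.0, 12.0]
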