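# EpoR-induced JAK-STAT signalling: cytoplasmic STAT5 is phosphorylated at the
# activated receptor, dimerizes, translocates to the nucleus and shuttles back
# (nucleocytoplasmic cycling). Structure and rate constants follow the
# classic core model of this pathway (Swameye-type, with the transport delay
# replaced by first-order export: delay equations are out of scope here).
# Units: concentrations normalized to initial STAT5, time in minutes.
# Observables: phosphorylated STAT5, total cytoplasmic STAT5 and the
# (known, measured) activated receptor profile.
name: jak-stat
species: [STAT5, STAT5p, STAT5d, STAT5n]
initial: {STAT5: 1.0, STAT5p: 0.0, STAT5d: 0.0, STAT5n: 0.0}
parameters: {k1: 0.05, k2: 2.46, k3: 0.1066, k4: 0.10658, kx: 0.15, kx2: 0.1}
inputs:
  # activated-receptor pulse, peak 1.0 at t = 10 min
  EpoRA: "1.8473*(t/5)^2*exp(-t/5)"
rates:
  STAT5: "-k1*STAT5*EpoRA + 2*k4*STAT5n"
  STAT5p: "k1*STAT5*EpoRA - k2*STAT5p^2"
  STAT5d: "0.5*k2*STAT5p^2 - k3*STAT5d"
  STAT5n: "k3*STAT5d - k4*STAT5n"
observables:
  pSTAT5: "STAT5p + 2*STAT5d"
  tSTAT5: "STAT5 + STAT5p + 2*STAT5d + 2*STAT5n"
  EpoRA: "EpoRA"
time:
  t0: 0
  grid: [0, 4, 8, 12, 16, 20, 24, 28, 32, 36, 40, 44, 48, 52, 56, 60]
rk_steps: 6
variants:
  # nominal model ignoring the back-translocation of nuclear STAT5 into the
  # cytoplasm (missing stimulatory interaction STAT5n -> STAT5)
  - name: no-nuclear-export
    mode: remove
    source: STAT5n
    target: STAT5
    sign: stim
    rates:
      STAT5: "-k1*STAT5*EpoRA"
      STAT5n: "k3*STAT5d"
  # nominal model missing the nuclear import of the STAT5 dimer
  # (missing stimulatory interaction STAT5d -> STAT5n)
  - name: missing-import
    mode: remove
    source: STAT5d
    target: STAT5n
    sign: stim
    rates:
      STAT5d: "0.5*k2*STAT5p^2"
      STAT5n: "-k4*STAT5n"
  # nominal model missing the dimerization of phosphorylated STAT5
  # (missing stimulatory interaction STAT5p -> STAT5d)
  - name: missing-dimerization
    mode: remove
    source: STAT5p
    target: STAT5d
    sign: stim
    rates:
      STAT5p: "k1*STAT5*EpoRA"
      STAT5d: "-k3*STAT5d"
  # nominal model with a spurious direct recycling of nuclear STAT5 to the
  # phosphorylated pool (wrong stimulatory interaction STAT5n -> STAT5p)
  - name: spurious-recycling
    mode: add
    source: STAT5n
    target: STAT5p
    sign: stim
    rates:
      STAT5p: "k1*STAT5*EpoRA - k2*STAT5p^2 + kx*STAT5n"
      STAT5n: "k3*STAT5d - k4*STAT5n - kx*STAT5n"
  # nominal model with a spurious dissociation of the cytoplasmic dimer back
  # to monomers (wrong stimulatory interaction STAT5d -> STAT5p)
  - name: spurious-dissociation
    mode: add
    source: STAT5d
    target: STAT5p
    sign: stim
    rates:
      STAT5p: "k1*STAT5*EpoRA - k2*STAT5p^2 + 2*kx2*STAT5d"
      STAT5d: "0.5*k2*STAT5p^2 - k3*STAT5d - kx2*STAT5d"
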