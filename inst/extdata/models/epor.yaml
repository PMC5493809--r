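# Information processing at the erythropoietin receptor: ligand binding,
# receptor turnover, internalization of the ligand-receptor complex,
# recycling and location-dependent degradation. Becker-type core model
# (pM, minutes). Observables combine ligand pools in medium, on the surface
# and inside cells.
name: epor
species: [Epo, EpoR, EpoEpoR, EpoEpoRi, dEpoi, dEpoe]
initial: {Epo: 2030, EpoR: 516, EpoEpoR: 0, EpoEpoRi: 0, dEpoi: 0, dEpoe: 0}
parameters: {kon: 0.000105, koff: 0.0172, kt: 0.0329, Bmax: 516, ke: 0.0748,
             kex: 0.00993, kdi: 0.00318, kde: 0.0164, kfb: 0.000005}
inputs: {}
rates:
  Epo: "-kon*Epo*EpoR + koff*EpoEpoR + kex*EpoEpoRi"
  EpoR: "kt*Bmax - kt*EpoR - kon*Epo*EpoR + koff*EpoEpoR + kex*EpoEpoRi"
  EpoEpoR: "kon*Epo*EpoR - koff*EpoEpoR - ke*EpoEpoR"
  EpoEpoRi: "ke*EpoEpoR - kex*EpoEpoRi - kdi*EpoEpoRi - kde*EpoEpoRi"
  dEpoi: "kdi*EpoEpoRi"
  dEpoe: "kde*EpoEpoRi"
observables:
  Epo_medium: "Epo + dEpoe"
  Epo_surface: "EpoEpoR"
  Epo_cells: "EpoEpoRi + dEpoi"
time:
  t0: 0
  grid: [0, 20, 60, 100, 140, 180, 240, 300]
variants:
  # nominal model with a wrong receptor-induced feedback consuming free Epo
  # (spurious inhibitory interaction EpoR -| Epo)
  - name: wrong-feedback
    mode: add
    source: EpoR
    target: Epo
    sign: inh
    rates:
      Epo: "-kon*Epo*EpoR + koff*EpoEpoR + kex*EpoEpoRi - kfb*Epo*EpoR"
      EpoR: "kt*Bmax - kt*EpoR - kon*Epo*EpoR + koff*EpoEpoR + kex*EpoEpoRi - kfb*Epo*EpoR"
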