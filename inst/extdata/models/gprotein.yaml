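# Heterotrimeric G protein cycle in yeast: receptor synthesis/turnover,
# ligand binding, G protein activation by the ligand-bound receptor, GTP
# hydrolysis and heterotrimer re-association. Fully observed test case
# (identity measurement). Parameter values follow the published yeast cycle
# model (molecules/cell, seconds); the re-association rate is reduced
# relative to the original so the cycle is non-stiff on the coarse sampling
# grid - a documented fixture reconstruction choice.
name: gprotein
species: [R, RL, G, Ga, Gd, Gbg]
initial: {R: 10000, RL: 0, G: 10000, Ga: 0, Gd: 0, Gbg: 0}
parameters: {kRs: 4.0, kRd0: 0.0004, kRd1: 0.004, kRLf: 0.2, kRLm: 0.01,
             kGa: 0.00001, kGd: 0.11, kG1: 0.00002, kw: 0.000005}
inputs: {}
rates:
  R: "kRs - kRd0*R - kRLf*R + kRLm*RL"
  RL: "kRLf*R - kRLm*RL - kRd1*RL"
  G: "-kGa*RL*G + kG1*Gd*Gbg"
  Ga: "kGa*RL*G - kGd*Ga"
  Gd: "kGd*Ga - kG1*Gd*Gbg"
  Gbg: "kGa*RL*G - kG1*Gd*Gbg"
observables:
  R: "R"
  RL: "RL"
  G: "G"
  Ga: "Ga"
  Gd: "Gd"
  Gbg: "Gbg"
time:
  t0: 0
  grid: [0, 10, 30, 60, 120, 210, 360, 600]
rk_steps: 48
variants:
  # nominal model with a wrong receptor-catalysed reactivation of inactive
  # G-alpha (spurious stimulatory interaction RL -> Gd)
  - name: wrong-reactivation
    mode: add
    source: RL
    target: Gd
    sign: stim
    rates:
      Ga: "kGa*RL*G - kGd*Ga + kw*RL*Gd"
      Gd: "kGd*Ga - kG1*Gd*Gbg - kw*RL*Gd"
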