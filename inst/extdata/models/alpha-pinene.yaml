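# Thermal isomerization of alpha-pinene in the liquid phase: racemized
# alpha-pinene isomerizes to dipentene and to allo-ocimene, which dimerizes
# reversibly. Four measured species (mass percent, minutes); rate constants
# of the classic kinetics benchmark, with the dimerization written as the
# second-order step 2 aO <-> Di.
name: alpha-pinene
species: [aP, dP, aO, Di]
initial: {aP: 100, dP: 0, aO: 0, Di: 0}
parameters: {k1: 0.0000593, k2: 0.0000296, k3: 0.000275, k4: 0.00004,
             k3b: 0.001}
inputs: {}
rates:
  aP: "-(k1 + k2)*aP"
  dP: "k1*aP"
  aO: "k2*aP - 2*k3*aO^2 + 2*k4*Di"
  Di: "k3*aO^2 - k4*Di"
observables:
  aP: "aP"
  dP: "dP"
  aO: "aO"
  Di: "Di"
time:
  t0: 0
  grid: [0, 1230, 3060, 4920, 7800, 10680, 15030, 22620, 36420]
variants:
  # nominal model with the bimolecular dimerization replaced by a first-order
  # step involving only allo-ocimene (the true 2 aO -> Di flux is missing)
  - name: missing-dimerization
    mode: remove
    source: aO
    target: Di
    sign: stim
    rates:
      aO: "k2*aP - k3b*aO"
      Di: "k3b*aO - k4*Di"
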