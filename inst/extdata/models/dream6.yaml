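# Gene-regulatory ring of six genes and six proteins in the style of the
# DREAM6 parameter-estimation challenge networks - SYNTHETIC reconstruction:
# alternating Hill activation and repression around the ring, mass-action
# translation and first-order decay. All proteins and one mRNA observable.
name: dream6
species: [m1, m2, m3, m4, m5, m6, p1, p2, p3, p4, p5, p6]
initial: {m1: 0.6, m2: 0.2, m3: 0.6, m4: 0.2, m5: 0.6, m6: 0.2,
          p1: 0.4, p2: 0.4, p3: 0.4, p4: 0.4, p5: 0.4, p6: 0.4}
parameters: {v: 1.0, K: 0.5, Kw: 0.5, h: 2, dm: 0.8, dp: 0.5, kt: 1.0}
inputs: {}
rates:
  m1: "v/(1 + (p6/K)^h) - dm*m1"
  m2: "v*(p1/K)^h/(1 + (p1/K)^h) - dm*m2"
  m3: "v/(1 + (p2/K)^h) - dm*m3"
  m4: "v*(p3/K)^h/(1 + (p3/K)^h) - dm*m4"
  m5: "v/(1 + (p4/K)^h) - dm*m5"
  m6: "v*(p5/K)^h/(1 + (p5/K)^h) - dm*m6"
  p1: "kt*m1 - dp*p1"
  p2: "kt*m2 - dp*p2"
  p3: "kt*m3 - dp*p3"
  p4: "kt*m4 - dp*p4"
  p5: "kt*m5 - dp*p5"
  p6: "kt*m6 - dp*p6"
observables:
  p1: "p1"
  p2: "p2"
  p3: "p3"
  p4: "p4"
  p5: "p5"
  p6: "p6"
  m1: "m1"
time:
  t0: 0
  grid: [0, 2, 4, 7, 10]
variants:
  # nominal model with a spurious repression of gene 4 by protein 6
  - name: wrong-repression
    mode: add
    source: p6
    target: m4
    sign: inh
    rates:
      m4: "v*(p3/K)^h/(1 + (p3/K)^h)/(1 + (p6/Kw)^h) - dm*m4"
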