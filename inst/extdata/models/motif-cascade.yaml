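# Three-step linear signalling cascade (canonical motif catalogue).
# Mass-flux kinetics: conversions carry the signal so a removed edge leaves
# compensating error terms on both participants. Rates are fixture choices.
name: motif-cascade
species: [A, B, C]
initial: {A: 0.1, B: 0.1, C: 0.1}
parameters: {kin: 1.0, kab: 0.8, kbc: 0.7, da: 0.3, db: 0.3, dc: 0.4, kca: 0.5}
inputs:
  stim: "5*t*exp(-1.2*t)"
rates:
  A: "kin*stim - kab*A - da*A"
  B: "kab*A - kbc*B - db*B"
  C: "kbc*B - dc*C"
observables:
  A: "A"
  B: "B"
  C: "C"
time:
  t0: 0
  grid: [0, 1, 2, 3, 4, 5, 6, 7, 8]
variants:
  - name: missing-conversion
    mode: remove
    source: A
    target: B
    sign: stim
    rates:
      A: "kin*stim - da*A"
      B: "-kbc*B - db*B"
  - name: wrong-recycling
    mode: add
    source: C
    target: A
    sign: stim
    rates:
      A: "kin*stim - kab*A - da*A + kca*C"
      C: "kbc*B - dc*C - kca*C"
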