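# Negative feedback loop: the end product C sequesters the upstream species A
# (inhibition as a biochemical flux consuming both partners).
name: motif-negative-feedback
species: [A, B, C]
initial: {A: 0.1, B: 0.1, C: 0.1}
parameters: {kin: 1.0, kab: 0.8, kbc: 0.7, da: 0.3, db: 0.3, dc: 0.4, ks: 1.5}
inputs:
  stim: "5*t*exp(-1.2*t)"
rates:
  A: "kin*stim - kab*A - da*A - ks*A*C"
  B: "kab*A - kbc*B - db*B"
  C: "kbc*B - dc*C - ks*A*C"
observables:
  A: "A"
  B: "B"
  C: "C"
time:
  t0: 0
  grid: [0, 1, 2, 3, 4, 5, 6, 7, 8]
variants:
  - name: missing-feedback
    mode: remove
    source: C
    target: A
    sign: inh
    rates:
      A: "kin*stim - kab*A - da*A"
      C: "kbc*B - dc*C"
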