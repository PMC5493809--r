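# Single-input fan-out: one upstream species distributed to three targets.
name: motif-fanout
species: [A, B, C, D]
initial: {A: 0.1, B: 0.1, C: 0.1, D: 0.1}
parameters: {kin: 1.0, kab: 0.6, kac: 0.5, kad: 0.4, da: 0.2, db: 0.3, dc: 0.3,
             dd: 0.4, kbc: 0.5}
inputs:
  stim: "5*t*exp(-1.2*t)"
rates:
  A: "kin*stim - kab*A - kac*A - kad*A - da*A"
  B: "kab*A - db*B"
  C: "kac*A - dc*C"
  D: "kad*A - dd*D"
observables:
  A: "A"
  B: "B"
  C: "C"
  D: "D"
time:
  t0: 0
  grid: [0, 1, 2, 3, 4, 5, 6, 7, 8]
variants:
  - name: missing-branch
    mode: remove
    source: A
    target: D
    sign: stim
    rates:
      A: "kin*stim - kab*A - kac*A - da*A"
      D: "-dd*D"
  - name: wrong-crosslink
    mode: add
    source: B
    target: C
    sign: stim
    rates:
      B: "kab*A - db*B - kbc*B"
      C: "kac*A + kbc*B - dc*C"
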