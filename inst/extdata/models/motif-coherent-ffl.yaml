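# Coherent feed-forward loop: A feeds C directly and through B.
name: motif-coherent-ffl
species: [A, B, C]
initial: {A: 0.1, B: 0.1, C: 0.1}
parameters: {kin: 1.0, kab: 0.8, kac: 0.4, kbc: 0.7, da: 0.2, db: 0.3, dc: 0.4}
inputs:
  stim: "5*t*exp(-1.2*t)"
rates:
  A: "kin*stim - kab*A - kac*A - da*A"
  B: "kab*A - kbc*B - db*B"
  C: "kac*A + kbc*B - dc*C"
observables:
  A: "A"
  B: "B"
  C: "C"
time:
  t0: 0
  grid: [0, 1, 2, 3, 4, 5, 6, 7, 8]
variants:
  - name: missing-shortcut
    mode: remove
    source: B
    target: C
    sign: stim
    rates:
      B: "kab*A - db*B"
      C: "kac*A - dc*C"
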