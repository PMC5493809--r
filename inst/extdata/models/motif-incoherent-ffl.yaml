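# Incoherent feed-forward loop: A produces C and (through B) removes it;
# the B -| C arm is a sequestration flux.
name: motif-incoherent-ffl
species: [A, B, C]
initial: {A: 0.1, B: 0.1, C: 0.1}
parameters: {kin: 1.0, kab: 0.8, kac: 0.6, da: 0.2, db: 0.3, dc: 0.3, ks: 1.5}
inputs:
  stim: "5*t*exp(-1.2*t)"
rates:
  A: "kin*stim - kab*A - kac*A - da*A"
  B: "kab*A - db*B - ks*B*C"
  C: "kac*A - dc*C - ks*B*C"
observables:
  A: "A"
  B: "B"
  C: "C"
time:
  t0: 0
  grid: [0, 1, 2, 3, 4, 5, 6, 7, 8]
variants:
  - name: missing-repression
    mode: remove
    source: B
    target: C
    sign: inh
    rates:
      B: "kab*A - db*B"
      C: "kac*A - dc*C"
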