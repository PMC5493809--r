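# Photomorphogenic UV-B signalling in Arabidopsis - SYNTHETIC reconstruction
# at the published dimensions (11 species, 5 observables combining 7
# species): UV-B monomerizes the UVR8 photoreceptor dimer, monomers bind
# COP1, the complex activates HY5/HYH transcription, HY5 induces RUP which
# promotes complex dissociation (negative feedback) and downstream CHS
# expression. Kinetics and rates are plausible fixture choices, not the
# published supplementary values. Time in hours.
name: uvb
species: [UVR8d, UVR8m, COP1, UC, HY5m, HY5, HYH, RUP, CHSm, CHS, FLS]
initial: {UVR8d: 2.0, UVR8m: 0.0, COP1: 1.5, UC: 0.0, HY5m: 0.1, HY5: 0.1,
          HYH: 0.05, RUP: 0.05, CHSm: 0.1, CHS: 0.1, FLS: 0.1}
parameters: {k1: 1.2, k2: 0.4, k3: 1.5, k4: 0.2, k5: 1.0,
             v1: 1.2, K1: 0.4, d1: 0.6, kt1: 1.0, dp1: 0.4,
             v2: 0.8, K2: 0.5, dp2: 0.4, v3: 0.7, K3: 0.5, d3: 0.3,
             v4: 0.9, K4: 0.5, v5: 0.4, K5: 0.5, d4: 0.5,
             kt3: 0.8, dp3: 0.3, v6: 0.5, K6: 0.5, d5: 0.3}
inputs:
  uv: "1"
rates:
  UVR8d: "-k1*uv*UVR8d + k2*UVR8m^2"
  UVR8m: "2*k1*uv*UVR8d - 2*k2*UVR8m^2 - k3*UVR8m*COP1 + k4*UC + k5*RUP*UC"
  COP1: "-k3*UVR8m*COP1 + k4*UC + k5*RUP*UC"
  UC: "k3*UVR8m*COP1 - k4*UC - k5*RUP*UC"
  HY5m: "v1*UC/(K1 + UC) - d1*HY5m"
  HY5: "kt1*HY5m - dp1*HY5"
  HYH: "v2*HY5/(K2 + HY5) - dp2*HYH"
  RUP: "v3*HY5/(K3 + HY5) - d3*RUP"
  CHSm: "v4*HY5/(K4 + HY5) + v5*HYH/(K5 + HYH) - d4*CHSm"
  CHS: "kt3*CHSm - dp3*CHS"
  FLS: "v6*HY5/(K6 + HY5) - d5*FLS"
observables:
  totUVR8m: "UVR8m + UC"
  UVR8d: "UVR8d"
  totHY5: "HY5 + HYH"
  CHSm: "CHSm"
  CHS: "CHS"
time:
  t0: 0
  grid: [0, 1, 2, 3, 4, 5, 6]
rk_steps: 12
variants:
  # nominal model missing the RUP-promoted dissociation of the UVR8m-COP1
  # complex (missing inhibitory interaction RUP -| UC)
  - name: missing-rup-feedback
    mode: remove
    source: RUP
    target: UC
    sign: inh
    rates:
      UVR8m: "2*k1*uv*UVR8d - 2*k2*UVR8m^2 - k3*UVR8m*COP1 + k4*UC"
      COP1: "-k3*UVR8m*COP1 + k4*UC"
      UC: "k3*UVR8m*COP1 - k4*UC"
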