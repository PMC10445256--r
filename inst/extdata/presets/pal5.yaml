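# Synthetic benchmark surface "pal5": a phenylalanine-ammonia-lyase-like
# hydroamination with five conditions and a reagent-solubility constraint
# 28.6*[NH4+] + 2*[DMSO] + 2.1*[PAL] < 200. SYNTHETIC fixture.
space:
  variables:
    - {name: cinnamate, lower: 10, upper: 100, units: mM, grid_points: 7}
    - {name: NH4, lower: 1, upper: 6, units: M, grid_points: 7}
    - {name: PAL, lower: 1, upper: 20, units: uM, grid_points: 7}
    - {name: pH, lower: 7, upper: 10, units: "", grid_points: 7}
    - {name: DMSO, lower: 5, upper: 30, units: "%", grid_points: 7}
  constraints:
    - coefficients: {NH4: 28.6, DMSO: 2, PAL: 2.1}
      limit: 200
      strict: true
roles:
  substrate: cinnamate
  cosubstrate: NH4
  enzyme: PAL
  ph: pH
  cosolvent: DMSO
params:
  ttn_max: 3000
  km: 30          # mM cinnamate
  ki: 2000        # weak substrate inhibition
  ph_opt: 8.5
  ph_width: 1.0
  cosolvent_decay: 0.04
  enzyme_half: 5  # uM
  cosubstrate_km: 2   # M NH4+, saturating (no inhibition)
  noise_cv: 0.05
optimum:
  point: {cinnamate: 100, NH4: 6, PAL: 1, pH: 8.5, DMSO: 5}
  TON: 1137.126045941641
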