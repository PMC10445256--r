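# Synthetic benchmark surface "bal6": a benzaldehyde-lyase-like
# cross-carboligation with six conditions and a second figure of merit
# (chemoselectivity, %) anti-correlated with TON. SYNTHETIC fixture.
space:
  variables:
    - {name: benzaldehyde, lower: 10, upper: 100, units: mM, grid_points: 5}
    - {name: isobutyraldehyde, lower: 10, upper: 100, units: mM, grid_points: 5}
    - {name: BAL, lower: 0.5, upper: 10, units: uM, grid_points: 5}
    - {name: pH, lower: 6, upper: 9, units: "", grid_points: 5}
    - {name: DMSO, lower: 5, upper: 30, units: "%", grid_points: 5}
    - {name: TPP, lower: 0.05, upper: 2, units: mM, grid_points: 5}
  constraints: []
roles:
  substrate: benzaldehyde
  cosubstrate: isobutyraldehyde
  enzyme: BAL
  ph: pH
  cosolvent: DMSO
  cofactor: TPP
params:
  ttn_max: 8000
  km: 25
  ki: 500         # substrate peak at sqrt(25*500) = 111.8 mM (just outside range)
  ph_opt: 7.5
  ph_width: 1.1
  cosolvent_decay: 0.02
  enzyme_half: 3
  cofactor_opt: 0.4
  cofactor_width: 0.8
  cosubstrate_km: 40
  noise_cv: 0.05
  selectivity:
    intercept: -1.0
    coef: {benzaldehyde: -0.03, isobutyraldehyde: -0.015, BAL: 0.4, DMSO: 0.08}
    noise_sd: 2
optimum:
  point: {benzaldehyde: 100, isobutyraldehyde: 100, BAL: 0.5, pH: 7.5, DMSO: 5, TPP: 0.5375}
  TON: 2967.482805382056
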