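# Synthetic benchmark surface "bfd5": a benzoylformate-decarboxylase-like
# carboligation with five continuous conditions, including a cofactor (TPP)
# optimum (excess TPP inhibits). SYNTHETIC fixture: mechanistically sensible
# functional forms, not measurements of any real enzyme.
space:
  variables:
    - {name: benzoylformate, lower: 10, upper: 200, units: mM, grid_points: 7}
    - {name: BFD, lower: 0.5, upper: 10, units: uM, grid_points: 7}
    - {name: pH, lower: 6, upper: 9, units: "", grid_points: 7}
    - {name: DMSO, lower: 0, upper: 30, units: "%", grid_points: 7}
    - {name: TPP, lower: 0.05, upper: 2, units: mM, grid_points: 7}
  constraints: []
roles:
  substrate: benzoylformate
  enzyme: BFD
  ph: pH
  cosolvent: DMSO
  cofactor: TPP
params:
  ttn_max: 6000
  km: 40          # mM
  ki: 400         # mM; TON-vs-substrate peak at sqrt(km*ki) = 126.5 mM
  ph_opt: 8
  ph_width: 1.2
  cosolvent_decay: 0.03   # per % DMSO
  enzyme_half: 4  # uM
  cofactor_opt: 0.3       # mM TPP
  cofactor_width: 0.6
  noise_cv: 0.05
# true optimum of the default 7-level candidate grid (noise-free surface)
optimum:
  point: {benzoylformate: 136.66666666666666, BFD: 0.5, pH: 8, DMSO: 0, TPP: 0.375}
  TON: 3212.68331140678
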