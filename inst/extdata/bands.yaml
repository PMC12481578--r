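serotonin:
  center:
  - 759.0
  - 934.0
  - 1134.0
  - 1310.0
  - 1425.0
  - 1547.0
  width:
  - 18.0
  - 22.0
  - 20.0
  - 24.0
  - 20.0
  - 26.0
  amplitude:
  - 1.0
  - 0.45
  - 0.6
  - 0.5
  - 0.35
  - 0.7
  shape:
  - lorentzian
  - lorentzian
  - lorentzian
  - lorentzian
  - lorentzian
  - lorentzian
dopamine:
  center:
  - 594.0
  - 769.0
  - 1151.0
  - 1269.0
  - 1332.0
  - 1485.0
  width:
  - 20.0
  - 18.0
  - 22.0
  - 20.0
  - 18.0
  - 24.0
  amplitude:
  - 0.5
  - 1.0
  - 0.55
  - 0.6
  - 0.8
  - 0.45
  shape:
  - lorentzian
  - lorentzian
  - lorentzian
  - lorentzian
  - lorentzian
  - lorentzian
epinephrine:
  center:
  - 640.0
  - 815.0
  - 1044.0
  - 1269.0
  - 1391.0
  - 1582.0
  width:
  - 22.0
  - 18.0
  - 20.0
  - 20.0
  - 22.0
  - 24.0
  amplitude:
  - 0.55
  - 1.0
  - 0.5
  - 0.45
  - 0.65
  - 0.6
  shape:
  - lorentzian
  - lorentzian
  - lorentzian
  - lorentzian
  - lorentzian
  - lorentzian
urine_background:
  center:
  - 525.0
  - 680.0
  - 1003.0
  - 1160.0
  - 1440.0
  - 1650.0
  width:
  - 120.0
  - 90.0
  - 30.0
  - 110.0
  - 140.0
  - 120.0
  amplitude:
  - 0.5
  - 0.45
  - 0.9
  - 0.6
  - 0.8
  - 0.55
  shape:
  - gaussian
  - gaussian
  - lorentzian
  - gaussian
  - gaussian
  - gaussian
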