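{
  "provenance": "simulator calibration: 72 datasets, depths 1e+06/5e+06/2e+07, enrichments 0.1/0.3/0.5/0.8, marks sharp/broad",
  "levels": {
    "2.5": [13.2372525834658, 17.91727247331, 18.2942798357447],
    "5.0": [17.6540749280084, 19.4109171848185, 30.25175],
    "10.0": [21.7567952768305, 36.04225, 52.7475]
  }
}
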