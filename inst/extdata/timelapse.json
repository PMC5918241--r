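{
  "type": "timelapse",
  "frameIntervalMin": 12,
  "durationH": 16,
  "anaphaseTimeH": 4,
  "releaseLeadH": 2.5,
  "assemblyTauH": 3.9087,
  "assemblyPlateau": 600,
  "splitRatePerH": 0,
  "rejoinRatePerH": 1,
  "coheredDistUm": [0.6, 0.1],
  "splitDistUm": [1.8, 3.0],
  "frapBleachTimeH": "none",
  "intensityPcm": 2000,
  "pixelSizeUm": 0.1,
  "fieldPx": 128,
  "psfSigmaUm": 0.1,
  "noiseGaussianSd": 2,
  "noisePoissonGain": 0.5
}
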