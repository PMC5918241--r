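{
  "type": "scene",
  "pixelSizeUm": 0.1,
  "fieldPx": 800,
  "nCells": 32,
  "pSplit": 0.10,
  "coheredDistUm": [0.6, 0.15],
  "splitDistUm": [1.8, 4.0],
  "distanceRangeUm": [0.3, 4.0],
  "nCentrioles": 2,
  "rootAreaScale": 10,
  "linkMidpointUm": 1.4,
  "linkSteepness": 0.05,
  "intensity": {"dna": 400, "centriole": 600, "pcm": 500, "rootletin": 300},
  "psfSigmaUm": 0.1,
  "noiseGaussianSd": 5,
  "noisePoissonGain": 0.25,
  "pMitotic": 0
}
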