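{
  "name": "B",
  "outcome": "Un-worsened",
  "description": "Published fixed-coefficient logistic model predicting the Un-worsened (CR+PR+SD) outcome from 4 standardized AEF texture features.",
  "intercept": 3.1287,
  "coefficients": {
    "Kurtosis": -0.5309,
    "ClusterProminence": 1.8890,
    "HighGreyLevelRunEmphasis": 0.5523,
    "LongRunHighGreyLevelEmphasis": 5.2633
  },
  "z": {
    "Kurtosis": -0.8292,
    "ClusterProminence": 1.7340,
    "HighGreyLevelRunEmphasis": 1.1414,
    "LongRunHighGreyLevelEmphasis": 0.0152
  },
  "p": {
    "Kurtosis": 0.407,
    "ClusterProminence": 0.083,
    "HighGreyLevelRunEmphasis": 0.254,
    "LongRunHighGreyLevelEmphasis": 0.988
  }
}
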