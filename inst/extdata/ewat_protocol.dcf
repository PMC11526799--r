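step: Interview with the mahout
minutes: 15

step: Observation of the daytime rest area
minutes: 5

step: Observation of the nighttime rest area
minutes: 5

step: Physical examination
minutes: 5

step: Behavioral observation (restricted state)
minutes: 15
note: 15 min observation; at least a 1-h gap between the two behavioral observations; limit mahout interaction; no food present in the evaluation area

step: Behavioral observation (non-restricted state)
minutes: 15
note: 15 min observation; at least a 1-h gap between the two behavioral observations; limit mahout interaction; no food present in the evaluation area
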