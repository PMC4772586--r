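# Worked-example model: affluence -> {emergency admission, hospital caseload}
# -> quarterly hazard of colon-cancer death, truncated at 24 periods.
exposure: affluence
outcome:
  time: time
  event: event
  J_max: 24
  baseline: unstructured
  proportional: true
equations:
  - dependent: emergency
    regressors: [age10, affluence]
    link: linear
  - dependent: caseload
    regressors: [age10, affluence, emergency]
    link: linear
  - dependent: hazard
    regressors: [age10, affluence, emergency, stageII, stageIII, stageIV, treatment, caseload]
    link: discrete_time_logit
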