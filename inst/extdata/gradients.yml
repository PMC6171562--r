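# HPLC gradient programs for the four acquisition methods.
# %B is the organic-phase fraction at each timetable breakpoint.
positive_underivatized:
  buffers: "A: 99.9% H2O / 0.1% formic acid; B: 99.9% methanol / 0.1% formic acid"
  column_temperature_c: 40
  flow_rate_ml_min: 0.4
  timetable:
    - {time_min: 0, percent_b: 0}
    - {time_min: 3, percent_b: 5}
    - {time_min: 10, percent_b: 60}
    - {time_min: 11, percent_b: 95}
    - {time_min: 14, percent_b: 95}
    - {time_min: 15, percent_b: 5}
    - {time_min: 16, percent_b: 0}
    - {time_min: 21, percent_b: 0}
negative_underivatized:
  buffers: "A: 5 mM ammonium acetate in H2O; B: 100% acetonitrile"
  column_temperature_c: 25
  flow_rate_ml_min: 0.4
  timetable:
    - {time_min: 0, percent_b: 0}
    - {time_min: 3, percent_b: 5}
    - {time_min: 10, percent_b: 60}
    - {time_min: 11, percent_b: 95}
    - {time_min: 14, percent_b: 95}
    - {time_min: 15, percent_b: 5}
    - {time_min: 16, percent_b: 0}
    - {time_min: 21, percent_b: 0}
obha_gradient1:
  buffers: "A: 99.9% H2O / 0.1% formic acid; B: 99.9% methanol / 0.1% formic acid"
  column_temperature_c: 40
  flow_rate_ml_min: 0.4
  timetable:
    - {time_min: 0, percent_b: 50}
    - {time_min: 2, percent_b: 75}
    - {time_min: 6, percent_b: 100}
    - {time_min: 15, percent_b: 100}
    - {time_min: 17, percent_b: 50}
    - {time_min: 21, percent_b: 50}
obha_gradient2:
  buffers: "A: 99.9% H2O / 0.1% formic acid; B: 99.9% methanol / 0.1% formic acid"
  column_temperature_c: 40
  flow_rate_ml_min: 0.4
  timetable:
    - {time_min: 0, percent_b: 50}
    - {time_min: 2, percent_b: 65}
    - {time_min: 12, percent_b: 90}
    - {time_min: 12.01, percent_b: 100}
    - {time_min: 15, percent_b: 100}
    - {time_min: 20, percent_b: 50}
    - {time_min: 26, percent_b: 50}
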