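# Default personalized-recommendation rules.
#
# These defaults encode standard behavioral sleep-medicine heuristics over
# the weekly diary aggregate (minutes / percent) and the latest ISI; they
# are a package reconstruction, not a published rule table, and are meant
# to be replaced wholesale by editing this file. Conditions use the
# restricted expression grammar (indicator names, numbers, comparisons,
# and/or/not). Lower priority = shown first.
rules:
  - id: restrict_tib
    condition: se < 85 & tib > 540
    advice: restrict_tib
    priority: 1
    params:
      reduce_minutes: 30
  - id: stimulus_control
    condition: sol > 30
    advice: stimulus_control
    priority: 2
  - id: fixed_rise_time
    condition: twak > 30
    advice: fixed_rise_time
    priority: 3
  - id: wind_down
    condition: nwak > 2 | waso > 30
    advice: wind_down
    priority: 4
  - id: limit_stimulants
    condition: se < 80 & sol > 20
    advice: limit_stimulants
    priority: 5
  - id: see_specialist
    condition: isi_total > 21
    advice: see_specialist
    priority: 6
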