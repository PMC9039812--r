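# Example scenario for the apartment simulator (synthetic data only).
# A single-resident apartment with two monitored kitchen routines, in the
# style of an end-user routine interview: activity windows, notification
# preference, and scheduled home-care visits.
apartment_id: "1"
routines:
  - {activity: breakfast, room: kitchen, start: "06:00", end: "09:00", preference: N/P}
  - {activity: lunch, room: kitchen, start: "11:00", end: "13:00", preference: N/P}
duration_models:
  breakfast: {family: lognormal, mean: 87, sd: 35}
  lunch: {family: lognormal, mean: 52, sd: 25}
n_days: 62
start_date: 2020-07-01
seed: 1
duplicate_rate: 0.05
home_care_dates: [2020-08-05, 2020-08-12, 2020-08-19, 2020-08-26]
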