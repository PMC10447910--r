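# Packaged default DIFFMASK point allocation (synthetic default honouring
# the published structure: ten components, theoretical range 0-18, monotone
# in every risk factor). Override by editing a copy and loading it with
# read_diffmask_weights().
age:
  breaks: [45.0, 60.0]
  points: [0, 1, 2]
gender:
  levels:
    female: 0
    male: 1
bmi:
  breaks: [25.0, 30.0]
  points: [0, 1, 2]
tmd:
  breaks: [4.0, 6.5]
  points: [2, 1, 0]
mmt:
  levels:
    "1": 0
    "2": 0
    "3": 1
    "4": 2
snoring:
  "yes": 2
neck_radiation:
  "yes": 2
difficult_intubation_history:
  "yes": 2
sleep_apnea:
  "yes": 2
beard:
  "yes": 1
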