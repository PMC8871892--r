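public_daily: 86
private_daily: 7
general_daily: 867
capacity:
  QMS: 2
  REVENUE: 4
  OG_COUNTER: 1
  VITALS: 2
  LAB: 2
  CONSULT: 10
  SPECIALIST: 3
  NURSES: 2
  PRIVATE_COUNTER: 1
  CONSULT_PRIV: 2
doctors: 7
specialists: 3
private_specialists: 2
rooms: 10
service:
  QMS:
    OBS:
    - 0.32
    - 0.52
    - 0.91
    GYN:
    - 0.32
    - 0.52
    - 0.91
    GENERAL:
    - 0.32
    - 0.52
    - 0.91
  REVENUE:
    OBS:
    - 0.57
    - 0.92
    - 1.61
    GYN:
    - 0.57
    - 0.92
    - 1.61
    GENERAL:
    - 0.57
    - 0.92
    - 1.61
  OG_COUNTER:
    OBS:
    - 0.5
    - 1.0
    - 2.0
    GYN:
    - 0.5
    - 1.0
    - 2.0
  VITALS:
    OBS:
    - 1.0
    - 2.0
    - 3.0
    GYN:
    - 1.0
    - 2.0
    - 4.0
    PRIVATE:
    - 1.0
    - 1.0
    - 1.0
  LAB:
    OBS:
    - 3.0
    - 4.0
    - 6.0
    GYN:
    - 3.0
    - 4.0
    - 6.0
    PRIVATE:
    - 2.0
    - 3.0
    - 4.0
  CONSULT:
    OBS:
    - 10.0
    - 13.0
    - 20.0
    GYN:
    - 7.0
    - 10.0
    - 17.0
  SPECIALIST:
    OBS:
    - 3.0
    - 5.0
    - 8.0
    GYN:
    - 3.0
    - 5.0
    - 8.0
  NURSES:
    OBS:
    - 1.0
    - 2.0
    - 4.0
    GYN:
    - 1.0
    - 2.0
    - 4.0
  PRIVATE_COUNTER:
    PRIVATE:
    - 2.0
    - 4.0
    - 7.0
  CONSULT_PRIV:
    PRIVATE:
    - 13.0
    - 17.0
    - 21.0
transfer: 2.0
public_consult_capacity: 7
emr_overhead:
- 4.0
- 7.0
- 11.0
private_session_earliest: 750.0
downtime_episodes_per_day: 2
downtime_duration:
- 15.0
- 45.0
downtime_window:
- 540.0
- 720.0
rates:
  obs_split: 0.504201680672
  lab_obs: 0.283333333333
  lab_gyn: 0.0
  lab_private: 0.65625
  specialist_discussion: 0.1
  elderly: 0.2
  new_case: 0.2
  walk_in: 0.0
public_block_weights: ~
general_open: 420.0
general_last_slot: 930.0
counters_close: 1050.0
clinic_open: 450.0
clinic_close: 1020.0
consult_close: 780.0
lunch_minutes: 60.0
private_slots: 4
calibrated: yes
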