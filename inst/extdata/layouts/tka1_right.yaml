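id: TKA1
procedure: TKA
side: right
room:
  width: 6.5
  height: 6.5
obstacles:
- id: anesthesia_gear
  x: 3.25
  'y': 5.9
  width: 1.2
  height: 0.8
- id: wp1_desk
  x: 0.3
  'y': 1.2
  width: 0.6
  height: 1.2
- id: wp2_desk
  x: 6.3
  'y': 0.7
  width: 0.4
  height: 1.4
- id: rack_r1
  x: 0.15
  'y': 4.1
  width: 0.3
  height: 1.0
- id: rack_r2
  x: 6.35
  'y': 4.1
  width: 0.3
  height: 1.0
destinations:
  WP1:
  - 1.05
  - 0.65
  WP2:
  - 5.65
  - 1.15
  R1:
  - 0.75
  - 4.05
  R2:
  - 5.75
  - 4.45
  ST1:
  - 3.35
  - 0.25
  ST2:
  - 0.55
  - 3.05
  AR:
  - 6.15
  - 5.35
  sterile_room_door:
  - 0.45
  - 2.75
  anesthesia_room_door:
  - 6.3
  - 5.5
furniture:
- id: OR
  kind: or_table
  x: 3.25
  'y': 3.3
  width: 0.64
  height: 2.0
- id: T1
  kind: instrument_table
  x: 2.25
  'y': 2.75
  width: 0.6
  height: 0.4
  table_angle: 0.0
- id: T2
  kind: instrument_table
  x: 1.5
  'y': 2.75
  width: 0.8
  height: 0.5
  table_angle: 45.0
- id: T3
  kind: instrument_table
  x: 1.2
  'y': 1.9
  width: 0.8
  height: 0.5
  table_angle: 90.0
- id: T4
  kind: instrument_table
  x: 2.25
  'y': 1.25
  width: 0.8
  height: 0.5
  table_angle: 180.0
agents:
- role: SU
  x: 2.75
  'y': 3.0
  facing:
  - 0.6
  - -0.8
- role: SN
  x: 2.25
  'y': 2.1
  facing:
  - -0.0
  - 1.0
- role: A1
  x: 2.75
  'y': 2.3
  facing:
  - 1.0
  - 0.0
- role: A2
  x: 3.8
  'y': 3.0
  facing:
  - -1.0
  - 0.0
- role: AN
  x: 3.25
  'y': 5.0
  facing:
  - -0.0
  - -1.0
- role: CIRC
  x: 5.45
  'y': 0.65
  facing:
  - -1.0
  - 0.0
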