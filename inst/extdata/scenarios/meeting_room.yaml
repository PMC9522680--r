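# Meeting room, 3 users among 15 occupants, 4 h.
# ach_per_h is a calibrated reconstruction (see car_closed.yaml).
name: meeting_room
volume_m3: 81
ach_per_h: 1.637
duration_h: 4
n_users: 3
n_occupants: 15
source_kind: evp
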