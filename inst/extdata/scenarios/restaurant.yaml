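# Restaurant, 15 users among 100 occupants, 2 h.
# ach_per_h is a calibrated reconstruction (see car_closed.yaml).
name: restaurant
volume_m3: 270
ach_per_h: 4.881
duration_h: 2
n_users: 15
n_occupants: 100
source_kind: evp
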