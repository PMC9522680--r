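# Car with a 3-inch window gap, 2 users among 4 occupants, 1 h.
# ach_per_h is a calibrated reconstruction (see car_closed.yaml).
name: car_open
volume_m3: 3.17
ach_per_h: 52.48
duration_h: 1
n_users: 2
n_occupants: 4
source_kind: evp
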