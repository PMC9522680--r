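# Car with closed windows, 2 users among 4 occupants, 1 h.
# ach_per_h is a reconstruction calibrated with calibrate_ach() against the
# reported nicotine intake for this space; no measured rate is available.
name: car_closed
volume_m3: 3.17
ach_per_h: 25.06
duration_h: 1
n_users: 2
n_occupants: 4
source_kind: evp
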