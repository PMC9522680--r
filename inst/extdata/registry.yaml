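# Constituent registry for the intake model.
# emission_factor: ug exhaled per mg e-liquid consumed (EVP source).
# sidestream_emission: ug per cigarette (Kentucky reference 1R4F); absent
#   where no sidestream data exist.
# exposure_limit: 8-h limit concentration, ug/m3.
# saturation omitted everywhere: constituents treated as fully volatile.
nicotine:
  emission_factor: 4.22
  sidestream_emission: 5600
  exposure_limit: 500
propylene_glycol:
  emission_factor: 83.86
  exposure_limit: 10000
glycerin:
  emission_factor: 162.12
  exposure_limit: 10000
formaldehyde:
  emission_factor: 0.0083
  sidestream_emission: 700
  exposure_limit: 920
acetaldehyde:
  emission_factor: 0
  sidestream_emission: 4200
  exposure_limit: 360000
  below_mdl: true
acrolein:
  emission_factor: 0
  sidestream_emission: 1300
  exposure_limit: 250
  below_mdl: true
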