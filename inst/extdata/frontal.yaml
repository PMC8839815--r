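camera_label: frontal
roi: ~
garment_threshold:
  L:
  - 25.466
  - 98.62
  a:
  - -46.336
  - 8.86
  b:
  - -31.446
  - 60.616
replacement_rgb:
- 27.0
- 131.0
- 135.0
water_lstar_range:
- 5.0
- 160.0
waterline_row: 97
min_blob_area: 3000
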