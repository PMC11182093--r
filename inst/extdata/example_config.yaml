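# Example acquisition configuration (synthetic values).
# Biometry and geometry keys consumed by the scale module.
axial_length_mm: 24.46
fov_deg: 1.75
pixels: 512
lens_power_d: 0
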