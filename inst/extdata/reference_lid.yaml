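type: plant
gain_heat_C_per_s: 0.8
gain_cool_C_per_s: 0.8
loss_coeff_per_s: 0.004102564102564
ambient_C: 25.0
max_pwm: 255
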