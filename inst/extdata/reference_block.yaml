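type: plant
gain_heat_C_per_s: 2.800642004133508
gain_cool_C_per_s: 5.364550460937305
loss_coeff_per_s: 0.000242260594683
ambient_C: 25.0
max_pwm: 255
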