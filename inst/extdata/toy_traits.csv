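"species","head_rate","eye_movement","axial_length"
"spA",14.2,6.3,11.8
"spB",19.5,9.8,13.6
"spC",26.1,13.4,15.1
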