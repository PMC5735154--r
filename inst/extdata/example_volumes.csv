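"subject_id","vol_left","vol_right"
"demo02",2.91,4.07
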