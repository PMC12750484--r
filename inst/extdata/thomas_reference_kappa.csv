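feature_id,reference
secretion_amount,0.87
secretion_color,0.86
mucosal_edema,0.48
erythema,0.40
mucosal_ridging,0.54
mucosal_pallor,0.64
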