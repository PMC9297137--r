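label,n
food_related,770
not_food_related,230
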