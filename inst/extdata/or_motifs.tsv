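motif_id	pattern
I	LHQPRYFDE
II	KAYDRYEQT
III	SERNKDTHS
IV	PNLNPERYG
V	KSTCGSHEL
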