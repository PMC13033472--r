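chr15	27837000	27838000	LINE
chr15	27844500	27845200	SINE
chr15	27874500	27875000	LINE
chr15	27878400	27878900	LTR
chr15	27965000	27965600	SINE
chr15	27973300	27973700	LINE
chr15	27979400	27979800	LINE
chr15	27984400	27984900	SINE
chr15	28001000	28001500	LTR
chr15	28017500	28018000	LINE
chr15	28020500	28021000	SINE
chr15	28073000	28073500	LINE
chr15	28079400	28079800	LTR
chr15	28094000	28094500	LINE
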