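set_id	gene_id
neurotrophin_signaling_like	g001
neurotrophin_signaling_like	g002
neurotrophin_signaling_like	g003
neurotrophin_signaling_like	g004
neurotrophin_signaling_like	g005
neurotrophin_signaling_like	g006
neurotrophin_signaling_like	g007
zinc_finger_like	g010
zinc_finger_like	g011
zinc_finger_like	g012
zinc_finger_like	g013
zinc_finger_like	g014
calcium_signaling_like	g020
calcium_signaling_like	g021
calcium_signaling_like	g022
calcium_signaling_like	g023
calcium_signaling_like	g024
calcium_signaling_like	g025
calcium_signaling_like	g026
calcium_signaling_like	g027
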