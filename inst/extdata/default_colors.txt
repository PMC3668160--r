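Opisthokonta	#E41A1C
Amoebozoa	#377EB8
Archaeplastida	#4DAF4A
Excavata	#984EA3
Stramenopila	#FF7F00
Alveolata	#A65628
Rhizaria	#F781BF
Discoba	#17BECF
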