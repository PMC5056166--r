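roi	antpost	laterality	channel
left anterior	anterior	left	F7
left anterior	anterior	left	F3
right anterior	anterior	right	F4
right anterior	anterior	right	F8
left central	central	left	T7
left central	central	left	C3
right central	central	right	C4
right central	central	right	T8
left posterior	posterior	left	P7
left posterior	posterior	left	P3
right posterior	posterior	right	P4
right posterior	posterior	right	P8
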