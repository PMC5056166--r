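roi	antpost	laterality	channel
left anterior	anterior	left	F7
left anterior	anterior	left	F5
left anterior	anterior	left	F3
left anterior	anterior	left	FT7
left anterior	anterior	left	FC5
left anterior	anterior	left	FC3
mid anterior	anterior	mid	F1
mid anterior	anterior	mid	FZ
mid anterior	anterior	mid	F2
mid anterior	anterior	mid	FC1
mid anterior	anterior	mid	FCZ
mid anterior	anterior	mid	FC2
right anterior	anterior	right	F4
right anterior	anterior	right	F6
right anterior	anterior	right	F8
right anterior	anterior	right	FC4
right anterior	anterior	right	FC6
right anterior	anterior	right	FT8
left central	central	left	T7
left central	central	left	C5
left central	central	left	C3
left central	central	left	TP7
left central	central	left	CP5
left central	central	left	CP3
mid central	central	mid	C1
mid central	central	mid	CZ
mid central	central	mid	C2
mid central	central	mid	CP1
mid central	central	mid	CPZ
mid central	central	mid	CP2
right central	central	right	C4
right central	central	right	C6
right central	central	right	T8
right central	central	right	CP4
right central	central	right	CP6
right central	central	right	TP8
left posterior	posterior	left	P7
left posterior	posterior	left	P5
left posterior	posterior	left	P3
left posterior	posterior	left	PO7
left posterior	posterior	left	PO5
left posterior	posterior	left	O1
mid posterior	posterior	mid	P1
mid posterior	posterior	mid	PZ
mid posterior	posterior	mid	P2
mid posterior	posterior	mid	PO3
mid posterior	posterior	mid	PO4
mid posterior	posterior	mid	OZ
right posterior	posterior	right	P4
right posterior	posterior	right	P6
right posterior	posterior	right	P8
right posterior	posterior	right	PO6
right posterior	posterior	right	PO8
right posterior	posterior	right	O2
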