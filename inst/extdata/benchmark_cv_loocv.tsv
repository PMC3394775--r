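dataset	selector	classifier	avg	sd
prostate	cfs	biohel	92	27
prostate	cfs	gassist	93	25
prostate	cfs	svm	89	31
prostate	cfs	rf	95	22
prostate	cfs	pam	90	30
prostate	plss	biohel	94	24
prostate	plss	gassist	92	27
prostate	plss	svm	93	25
prostate	plss	rf	93	25
prostate	plss	pam	93	25
prostate	rfs	biohel	88	32
prostate	rfs	gassist	93	25
prostate	rfs	svm	89	31
prostate	rfs	rf	91	29
prostate	rfs	pam	91	29
prostate	none	biohel	92	27
lymphoma	cfs	biohel	84	36
lymphoma	cfs	gassist	87	34
lymphoma	cfs	svm	88	32
lymphoma	cfs	rf	87	34
lymphoma	cfs	pam	84	37
lymphoma	plss	biohel	92	26
lymphoma	plss	gassist	92	27
lymphoma	plss	svm	94	25
lymphoma	plss	rf	90	31
lymphoma	plss	pam	86	35
lymphoma	rfs	biohel	88	32
lymphoma	rfs	gassist	88	32
lymphoma	rfs	svm	90	31
lymphoma	rfs	rf	92	27
lymphoma	rfs	pam	83	38
lymphoma	none	biohel	94	25
breast	cfs	biohel	82	38
breast	cfs	gassist	84	36
breast	cfs	svm	84	37
breast	cfs	rf	84	36
breast	cfs	pam	90	30
breast	plss	biohel	84	37
breast	plss	gassist	84	36
breast	plss	svm	81	39
breast	plss	rf	88	33
breast	plss	pam	86	35
breast	rfs	biohel	82	39
breast	rfs	gassist	85	36
breast	rfs	svm	86	35
breast	rfs	rf	87	34
breast	rfs	pam	88	32
breast	none	biohel	86	35
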