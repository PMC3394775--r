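dataset	selector	classifier	avg	sd
prostate	cfs	biohel	91	8
prostate	cfs	gassist	93	10
prostate	cfs	svm	90	10
prostate	cfs	rf	92	11
prostate	cfs	pam	91	10
prostate	plss	biohel	92	8
prostate	plss	gassist	93	9
prostate	plss	svm	90	11
prostate	plss	rf	92	9
prostate	plss	pam	94	8
prostate	rfs	biohel	89	8
prostate	rfs	gassist	92	12
prostate	rfs	svm	88	8
prostate	rfs	rf	93	9
prostate	rfs	pam	90	11
prostate	none	biohel	94	8
lymphoma	cfs	biohel	81	10
lymphoma	cfs	gassist	80	15
lymphoma	cfs	svm	87	12
lymphoma	cfs	rf	87	16
lymphoma	cfs	pam	78	17
lymphoma	plss	biohel	93	12
lymphoma	plss	gassist	94	6
lymphoma	plss	svm	91	13
lymphoma	plss	rf	87	8
lymphoma	plss	pam	86	11
lymphoma	rfs	biohel	91	11
lymphoma	rfs	gassist	89	13
lymphoma	rfs	svm	91	13
lymphoma	rfs	rf	89	13
lymphoma	rfs	pam	86	14
lymphoma	none	biohel	95	8
breast	cfs	biohel	84	11
breast	cfs	gassist	87	8
breast	cfs	svm	86	9
breast	cfs	rf	86	7
breast	cfs	pam	89	7
breast	plss	biohel	84	7
breast	plss	gassist	85	5
breast	plss	svm	84	7
breast	plss	rf	89	5
breast	plss	pam	88	7
breast	rfs	biohel	86	5
breast	rfs	gassist	88	6
breast	rfs	svm	80	17
breast	rfs	rf	89	5
breast	rfs	pam	88	7
breast	none	biohel	88	5
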