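pattern	datatype	suffix	priority
tfl3d	anat	T1w	80
mprage	anat	T1w	80
t1w	anat	T1w	70
t1	anat	T1w	40
t2w	anat	T2w	70
tse	anat	T2w	60
space	anat	T2w	50
flair	anat	FLAIR	80
t2_fl	anat	FLAIR	70
sbref	func	sbref	90
bold	func	bold	80
fmri	func	bold	70
task	func	bold	50
rest	func	bold	50
dwi	dwi	dwi	80
dti	dwi	dwi	80
diff	dwi	dwi	60
spinecho	fmap	epi	90
sefmap	fmap	epi	90
topup	fmap	epi	90
distortion	fmap	epi	85
gre_field	fmap	phasediff	75
fieldmap	fmap	phasediff	70
field_map	fmap	phasediff	70
pcasl	perf	asl	90
pasl	perf	asl	85
asl	perf	asl	80
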