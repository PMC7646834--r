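pathologist	patient	msi_diagnosis	lcms_diagnosis	conclusion
RO	839	RO/ChRCC	RO	RO
RO	119	RO	RO	RO
RO	527	RO	RO	RO
RO	270	RO	RO	RO
RO	529	RO/ChRCC	RO	RO
RO	560	RO	RO	RO
RO	940	RO	RO	RO
RO	857	RO	RO	RO
RO	381	RO	RO	RO
ccRCC	427	ccRCC	ccRCC	ccRCC
ccRCC	370	ccRCC	ccRCC	ccRCC
ccRCC	620	ccRCC	ccRCC	ccRCC
ccRCC	73	ccRCC	ccRCC	ccRCC
ccRCC	545	ccRCC	ccRCC	ccRCC
ccRCC	999	ccRCC	ccRCC	ccRCC
ccRCC	797	RO	ccRCC	ccRCC/further validation
ccRCC	601	ccRCC	ccRCC	ccRCC
ccRCC	336	ccRCC	ccRCC	ccRCC
ChRCC	634	ChRCC	ChRCC	ChRCC
ChRCC	835	ChRCC	ChRCC	ChRCC
ChRCC	264	ChRCC with irregularities	ChRCC with irregularities	further validation -> sarcomatoid transformation
ChRCC	756	ChRCC	ChRCC	ChRCC
ChRCC	925	ChRCC	ChRCC	ChRCC
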