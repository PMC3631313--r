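sample_id	gene	chrom	pos	ref	alt	consequence	sift	polyphen	conserved	in_population_db	in_control_exomes
T001	SETD2	3	47057898	C	T	frameshift	unknown	unknown	1	0	0
T002	SETD2	3	47058898	C	T	frameshift	unknown	unknown	1	0	0
T003	SETD2	3	47059898	C	T	frameshift	unknown	unknown	1	0	0
T004	SETD2	3	47060898	C	T	nonsense	unknown	unknown	1	0	0
T005	SETD2	3	47061898	C	T	splice_site	unknown	unknown	1	0	0
T006	SETD2	3	47062898	C	T	missense	damaging	damaging	1	0	0
T007	SETD2	3	47063898	C	T	missense	damaging	damaging	1	0	0
T008	SETD2	3	47064898	C	T	missense	damaging	damaging	1	0	0
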