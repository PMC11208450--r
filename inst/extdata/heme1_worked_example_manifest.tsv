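#name	Heme 1 worked example panel
probe_id	kind	fusion_id	tube	lineages
POS_A	POS_CONTROL
POS_B	POS_CONTROL
POS_C	POS_CONTROL
POS_D	POS_CONTROL
POS_E	POS_CONTROL
POS_F	POS_CONTROL
NEG_A	NEG_CONTROL
NEG_B	NEG_CONTROL
NEG_C	NEG_CONTROL
NEG_D	NEG_CONTROL
NEG_E	NEG_CONTROL
NEG_F	NEG_CONTROL
BCR(ex1):ABL1(ex3)	FUSION	BCR::ABL1	HEME1	B-ALL;CML
BCR(ex1):JAK2(ex15)	FUSION	BCR::JAK2	HEME1	B-ALL
BCR(ex14):ABL1(ex2)	FUSION	BCR::ABL1	HEME1	B-ALL;CML
CBFB(ex5):MYH11 (type A)(ex33)	FUSION	CBFB::MYH11	HEME1	AML
CBFB(ex5):MYH11 (type B)(ex31)	FUSION	CBFB::MYH11	HEME1	AML
EBF1(ex15):PDGFRB(ex11)	FUSION	EBF1::PDGFRB	HEME1	B-ALL
ETV6(ex3):RUNX1(ex3)	FUSION	ETV6::RUNX1	HEME1	B-ALL
ETV6(ex4):JAK2(ex16)	FUSION	ETV6::JAK2	HEME1	B-ALL
PML(ex6):RARA(ex3)	FUSION	PML::RARA	HEME1	AML
RBM15(ex1):MKL1(ex4)	FUSION	RBM15::MKL1	HEME1	AML
RUNX1(ex6):MECOM(ex2)	FUSION	RUNX1::MECOM	HEME1	AML
RUNX1(ex6):RUNX1T1(ex2)	FUSION	RUNX1::RUNX1T1	HEME1	AML
TCF3(ex16):PBX1(ex3)	FUSION	TCF3::PBX1	HEME1	B-ALL
B2M	HOUSEKEEPING
EEF2	HOUSEKEEPING
GUSB	HOUSEKEEPING
PGK1	HOUSEKEEPING
TBP	HOUSEKEEPING
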