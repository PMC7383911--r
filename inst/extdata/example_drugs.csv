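# Worked-example drug parameters for SILM feasibility assessment.
# Units: dose_ug, microdose_ug in micrograms; vd_f_L in litres; t_half_h in
# hours; cmax_ss_ng_ml in ng/mL.
# ibrutinib: Vd/F back-computed from its 0.010 ng/mL theoretical microdose Cmax.
# abemaciclib: synthetic/back-computed row; Vd/F 690 L reproduces an 18.1 pg/mL
# required LLOQ and cmax_ss 200 ng/mL is a literature-typical steady-state value.
drug,formula,dose_ug,vd_f_L,t_half_h,cmax_ss_ng_ml,microdose_ug
ibrutinib,C25H24N6O2,560000,10000,6,221,100
abemaciclib,C27H32F2N8,150000,690,18.3,200,100
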