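# Curated 41-lipid marker array for spinal tumor-type discrimination by
# negative-mode ambient MS (0.1 Da spectral bins over 100-1000 Da).
# Columns:
#   bin          canonical 0.1-Da spectral bin label (midpoint of [lo, lo+0.1))
#   bin_printed  bin label as printed in the source identification table
#   target_mz    locked-mass target m/z observed in the ambient-MS profiles
#   adduct       ion adduct form
#   assignment   lipid assignment from high-resolution LC-MS/MS
# One printed label (Cer(d34:0), 574.55) is inconsistent with its own target
# and theoretical masses (574.4844 / 574.4972, both in [574.4, 574.5)); the
# canonical bin corrects it to 574.45. All other 40 rows agree.
bin	bin_printed	target_mz	adduct	assignment
860.65	860.65	860.6646	[M-H]-	PE(O-46:6)
846.65	846.65	846.6531	[M+Cl]-	HexCer(d42:1)
844.65	844.65	844.6404	[M+Cl]-	HexCer(d42:2)
830.65	830.65	830.6498	[M-H]-	PE(O-44:7)
826.65	826.65	826.6313	[M-H]-	HexCer(d42:1(OH))
818.65	818.65	818.6290	[M+Cl]-	HexCer(d40:1)
816.55	816.55	816.5457	[M+H]-	PS(38:1)
794.55	794.55	794.5651	[M-CH3]-	PC(38:4)
770.55	770.55	770.5630	[M-CH3]-	PC(36:2)
768.55	768.55	768.5399	[M-CH3]-	PC(36:3)
764.55	764.55	764.5359	[M-H]-	PE(38:5)
750.55	750.55	750.5397	[M+H]-	PE(O-38:5)
746.55	746.55	746.5496	[M-H]-	PE(O-38:7)
744.55	744.55	744.5493	[M-CH3]-	PC(34:1)
722.55	722.55	722.5268	[M-H]-	PE(O-36:5)
718.55	718.55	718.5203	[M-CH3]-	PC(32:0)
709.45	709.45	709.4800	[M+Cl]-	SM(d32:1)
704.55	704.55	704.5112	[M-CH3]-	PC(31:0)
698.65	698.65	698.6232	[M+Cl]-	Cer(d43:1)
698.55	698.55	698.5864	[M-H]-	HexCer(d34:1)
686.65	686.65	686.6032	[M+Cl]-	Cer(d42:0)
686.55	686.55	686.5285	[M-H]-	PE(O-33:2)
685.45	685.45	685.4817	[M-CH3]-	SM(d34:2)
672.55	672.55	672.5754	[M+Cl]-	Cer(d41:0)
668.55	668.55	668.5808	[M+Cl]-	Cer(d41:2)
661.45	661.45	661.4802	[M-CH3]-	SM(d32:0)
659.55	659.55	659.5202	[M-CH3]-	SM(d32:1)
658.55	658.55	658.5789	[M+Cl]-	Cer(d40:0)
656.55	656.55	656.5726	[M+Cl]-	Cer(d40:1)
654.55	654.55	654.5626	[M+Cl]-	Cer(d40:2)
642.55	642.55	642.5573	[M+Cl]-	Cer(d39:1)
631.45	631.45	631.4893	[M-CH3]-	SM(d30:1)
626.55	626.55	626.5344	[M+Cl]-	Cer(d38:2)
598.45	598.45	598.4959	[M+Cl]-	Cer(d36:2)
588.45	588.45	588.4729	[M+Cl]-	Cer(d34:1(OH))
574.45	574.55	574.4844	[M+Cl]-	Cer(d34:0)
570.45	570.45	570.4614	[M+Cl]-	Cer(d34:2)
365.35	365.35	365.3411	[M-H]-	FA 24:1
331.25	331.25	331.2614	[M-H]-	FA 22:4
329.25	329.25	329.2461	[M-H]-	FA 22:5
271.25	271.25	271.2226	[M-H]-	FA 16:0;O
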