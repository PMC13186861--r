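name	aa_start	aa_end
PALB2_BD	21	39
RAD51_BD_BRC	1002	2085
Helical	2481	2667
OB_fold_1	2670	2803
OB_fold_2	2809	3048
OB_fold_3	3052	3190
DBD	2481	3190
CT_RAD51_BD	3265	3330
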