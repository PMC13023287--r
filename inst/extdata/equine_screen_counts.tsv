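# Reported TFO1 overlapping-triplex counts, CpG-island overlaps and
# accessible-region overlaps for the eleven gene-lncRNA pairs of the equine
# reproductive-efficiency screen that motivated this package's defaults.
gene	lncrna	target	shuffled_lncrna	shuffled_target	control	cpg_overlap	accessible_overlap
ERCC1	lnc129946	35	4	2	14	4	35
HTRA3	lnc82066	25	11	2	1	24	25
PRSS21	lnc140240	22	1	2	5	15	22
PRSS21	lnc143931	17	2	1	2	5	17
HTRA3	lnc117842	14	8	1	1	14	14
ERCC1	lnc134182	9	2	1	2	0	9
HTRA3	lnc92675	8	2	1	1	7	0
FOXA3	lnc122996	6	2	2	3	5	6
ERCC1	lnc90102	3	1	1	0	0	2
ERCC1	lnc85946	3	9	1	3	0	1
PRSS21	lnc86008	2	2	1	1	0	0
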