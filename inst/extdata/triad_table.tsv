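# Hoogsteen triad stability weights used by scan_triplexes().
# orientation: parallel (pyrimidine motif) or antiparallel (purine motif)
# rna: third-strand RNA base; dna: base on the scanned strand of the duplex
# weight: 2 = canonical triad, 1 = documented weak triad; omitted keys are 0
orientation	rna	dna	weight
parallel	U	A	2
parallel	C	G	2
parallel	G	G	1
parallel	G	T	1
antiparallel	A	A	2
antiparallel	G	G	2
antiparallel	U	A	2
antiparallel	C	A	1
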