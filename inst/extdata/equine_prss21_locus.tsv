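# Genomic coordinates (EquCab3.0, ECA13) of the PRSS21 / lnc140240 worked
# example: target gene span and TSS, the lncRNA locus, and the CpG island
# overlapping the predicted binding region in the PRSS21 promoter.
feature	name	chrom	start	end	strand
gene	PRSS21	ECA13	41173894	41211128	+
tss	PRSS21	ECA13	41174024	41174024	+
lncrna_locus	lnc140240	ECA13	41160959	41163821	*
cpg_island	PRSS21_promoter	ECA13	41174357	41175187	*
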