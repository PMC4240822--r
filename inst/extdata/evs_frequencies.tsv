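chrom	pos	ref	alt	freq
chr2	208989018	C	A	0/8,600
chr1	147380102	T	C	0/8,600
chr1	147380375	A	C	0/8,600
chr10	91222287	T	G	731/8,600
chr4	6280000	A	G	4,703/8,600
chr20	17500000	G	A	2,214/8,600
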