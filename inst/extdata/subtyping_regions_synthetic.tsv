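region_id	chrom	start	end
chr1p	1	1	45000000
chr1q	1	55000001	100000000
chr2p	2	1	45000000
chr2q	2	55000001	100000000
chr3p	3	1	45000000
chr3q	3	55000001	100000000
chr4p	4	1	45000000
chr4q	4	55000001	100000000
chr5p	5	1	45000000
chr5q	5	55000001	100000000
chr6p	6	1	45000000
chr6q	6	55000001	100000000
chr7p	7	1	45000000
chr7q	7	55000001	100000000
chr8p	8	1	45000000
chr8q	8	55000001	100000000
chr9p	9	1	45000000
chr9q	9	55000001	100000000
chr10p	10	1	45000000
chr10q	10	55000001	100000000
chr11p	11	1	45000000
chr11q	11	55000001	100000000
chr12p	12	1	45000000
chr12q	12	55000001	100000000
chr13p	13	1	45000000
chr13q	13	55000001	100000000
chr14p	14	1	45000000
chr14q	14	55000001	100000000
chr15p	15	1	45000000
chr15q	15	55000001	100000000
chr16p	16	1	45000000
chr16q	16	55000001	100000000
chr17p	17	1	45000000
chr17q	17	55000001	100000000
chr18p	18	1	45000000
chr18q	18	55000001	100000000
chr19p	19	1	45000000
chr19q	19	55000001	100000000
chr20p	20	1	45000000
chr20q	20	55000001	100000000
chr21p	21	1	45000000
chr21q	21	55000001	100000000
chr22p	22	1	45000000
chr22q	22	55000001	100000000
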