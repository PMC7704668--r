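# SYNTHETIC stand-in gene-coordinate table for the bovine reference
# mitogenome (16,338 bp, 1-based inclusive coordinates, linearised at np 1).
# The 13 protein-coding genes follow the standard vertebrate mtDNA gene
# order and strand layout (ND6 is the single L-strand gene); the exact
# boundaries here are NOT a curated annotation -- replace this file with one
# derived from your annotation source before analysing real mitogenomes.
# All lengths are multiples of 3; total coding length 11,397 bp.
gene	start	end	strand
ND1	2903	3859	H
ND2	4070	5113	H
COX1	5487	7031	H
COX2	7172	7855	H
ATP8	7926	8126	H
ATP6	8130	8810	H
COX3	8813	9592	H
ND3	9662	10006	H
ND4L	10077	10373	H
ND4	10380	11756	H
ND5	11957	13777	H
ND6	13781	14305	L
CYTB	14310	15449	H
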