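# Cattle mtDNA haplogroup motif table (BRS coordinates).
# The root is the reference lineage (T3, the haplogroup of the reference
# mitogenome): a profile with no variants classifies as T3.  Branches whose
# complete diagnostic motifs are not published are `provisional` with empty
# variant lists; edit this file to extend the nomenclature.
# P1a is defined by six diagnostic transitions; the one at np 16247 falls in
# the 410-bp control-region window and suffices for control-region-only
# classification.
name	parent	status	variants
T3	-	defined
T1	T3	provisional
T2	T3	provisional
T5	T3	provisional
I	T3	provisional
I1	I	provisional
I2	I	provisional
Q	T3	provisional
Q1	Q	provisional
Q2	Q	provisional
R	T3	provisional
R1	R	provisional
R2	R	provisional
P	T3	provisional
P1	P	provisional
P1a	P1	defined	2171,5681,11468,12738,15714,16247
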