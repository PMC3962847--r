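sample	raw	high_quality	chimeras
A1	4235	3054	422
A2	5947	4229	783
O1	15967	7474	412
O2	17522	6215	363
O3	22714	4836	396
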