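infant	microbial_groups	human_groups	total_groups
03	9318	3250	12568
19	7397	2268	9665
21	6349	742	7091
23	10330	1319	11649
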