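AF099922_synthetic	7946	8058	.	0	.
AF099922_synthetic	9547	9878	.	0	.
AF099922_synthetic	11133	11396	.	0	.
AF099922_synthetic	12484	12663	.	0	.
AF099922_synthetic	14274	14624	.	0	.
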