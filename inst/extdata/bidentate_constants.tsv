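system	log_k_or	log_k_cr	pk1	k_plus_cr_s	k_minus_cr_s
cd-en	0.6	4.5	5.1	6.8e9	NA
ni-en	0.7	6.4	7.1	7.2e9	2.9e3
cd-put	1.9	1.2	3.1	NA	NA
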