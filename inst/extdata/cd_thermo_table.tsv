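species	n	delta_g	delta_h	minus_t_delta_s	delta_h_per_n	minus_t_delta_s_per_n
nme_1	1	-14.2	-23.0	8.8	-23.0	8.8
nme_2	2	-26.8	-46.9	20.1	-23.5	10.1
nme_3	3	-32.6	-63.2	30.5	-21.1	10.2
nme_4	4	-33.1	-81.6	48.5	-20.4	12.1
nme_6	6	-15.9	-98.7	82.8	-16.5	13.8
en_1	2	-29.3	-43.5	14.2	-21.8	7.1
en_2	4	-51.9	-87.0	35.1	-21.8	8.8
en_3	6	-62.7	-119.2	56.4	-19.9	9.4
dien_1	3	-38.9	-53.4	15.5	-17.8	5.2
dien_2	6	-61.1	-100.4	39.3	-16.7	6.6
put_1	2	-18.0	-45.6	27.6	-22.8	13.8
put_2	4	-31.8	-89.1	57.3	-22.3	14.3
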