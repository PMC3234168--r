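doc_id	ratio_pct	expert_label
Post 1	4.59	yes
Post 2	5.05	no
Post 3	4.31	no
Post 4	4.18	no
Post 5	2.80	no
Post 6	4.46	no
Post 7	8.47	yes
Post 8	3.03	no
Post 9	6.83	yes
Post 10	4.84	yes
Post 11	9.09	yes
Post 12	6.74	yes
Post 13	7.63	yes
Post 14	4.73	no
Post 15	7.09	yes
Post 16	8.15	yes
Post 17	3.81	yes
Post 18	3.44	no
Post 19	7.77	yes
Post 20	6.83	yes
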