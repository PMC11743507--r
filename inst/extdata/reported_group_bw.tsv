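group	week	mean_bw	sd_bw
CD+SPSS	4	22.65	0.95
CD+SPSS	10	26.00	2.92
HFD+SPSS	4	29.68	2.40
HFD+SPSS	10	35.20	4.87
HFD+PA	4	26.12	2.26
HFD+PA	10	23.00	2.45
HFD+Rutin	4	25.39	1.98
HFD+Rutin	10	24.80	1.30
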