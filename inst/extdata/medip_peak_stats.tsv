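# Published MACS peak summaries per line for the same panel.
# peak_mean_length is derivable as peak_total_length / total_peaks.
line_id	total_peaks	peak_mean_length_printed	peak_total_length	peak_genome_coverage_pct
P1	21355	1697.33	36246472	8.69
P2	18754	1791.66	33600816	8.06
H1	22932	1617.75	37098304	8.89
H2	24114	1418.43	34203905	8.20
H3	21582	1633.20	35247816	8.45
L1	18699	1705.54	31891918	7.65
L2	17711	1861.72	32972998	7.90
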