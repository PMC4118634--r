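# Published per-line MeDIP-Seq mapping summary for a Populus deltoides
# parent (P1, P2) / F1 hybrid (H1-H3 better-parent, L1-L2 lower-parent)
# leaf methylome panel; 49-bp single-end reads.
# mapped_rate_printed / unique_rate_printed are the rates as printed in
# the source table (1 decimal; H1 mapped rate was printed truncated as
# 82.4 although 80814131/97959184 = 82.4976%).
# L1 unique_reads was printed with malformed digit grouping
# ("438,630,69"); recorded here as 43863069, the only reading consistent
# with the printed 53.0% unique rate.
line_id	read_length	total_reads	mapped_reads	mapped_rate_printed	mapped_bases	unique_reads	unique_bases	unique_rate_printed
P1	49	97959184	81729006	83.4	4004721294	65078019	3188822931	66.4
P2	49	97959184	72679485	74.2	3561294765	55648568	2726779832	56.8
H1	49	97959184	80814131	82.4	3959892419	64231654	3147351046	65.6
H2	49	97959184	63730201	65.1	3122779849	54140276	2652873524	55.3
H3	49	97959184	64510366	65.9	3161007934	50943321	2496222729	52.0
L1	49	82792658	52534101	63.5	2574170949	43863069	2149290381	53.0
L2	49	97959184	70275601	71.7	3443504449	54474434	2669247266	55.6
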