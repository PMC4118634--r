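# Published CG/CHG/CHH context coverage (% of context sites covered at
# >= 1x MeDIP-Seq depth) for the parents, the better-parent hybrid H1
# and the lower-parent hybrid L1.
line_id	context	coverage_pct
P1	CG	17.24
P1	CHG	19.24
P1	CHH	18.83
P2	CG	12.61
P2	CHG	13.35
P2	CHH	12.92
H1	CG	16.97
H1	CHG	18.79
H1	CHH	18.44
L1	CG	10.21
L1	CHG	10.21
L1	CHH	10.05
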