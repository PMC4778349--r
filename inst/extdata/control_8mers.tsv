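motif	effect	role	sim_expression_effect	sim_stability_effect
AGGUAAGU	Repressive	Novel	-1.8	-0.7
ACAGGGUA	Repressive	miR-10 target site	-1.2	-0.55
CUACCUCA	Repressive	let-7 target site	-0.7	-0.35
UUCCGUUA	No_effect	miR-191 target site	0	0
UAAUGCCC	No_effect	Novel	0	0
UGUACAUA	Activating	Pumilio binding motif	0.5	0.3
UAUUUAUU	Activating	AU-rich element	0.9	0.4
UGUAAAGA	Activating	Novel	1.3	0.5
GUGAGUUU	Activating	Novel	1.7	0.6
GUUGCAUU	Activating	Novel	2.1	0.7
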