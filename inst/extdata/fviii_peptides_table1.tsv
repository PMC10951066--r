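peptide_id	sequence	domain
P285-304	VHSIFLEGHTFLVRNHRQAS	A1
P292-311	GHTFLVRNHRQASLEISPIT	A1
P75-94	DHLFNIAKPRPPWMGLLGPT	A1
P100-119	YDTVVITLKNMASHPVSLHA	A1
P322-341	LGQFLLFCHISSHQHDGMEA	a1
P20-39	ATRRYYLGAVELSWDYMQSD	A1
P178-197	LSHVDLVKDLNSGLIGALLV	A1
P1940-1959	INGYIMDTLPGLVMAQDQRI	A3
P2084-2103	KEPFSWIKVDLLAPMIIHGI	C1
P2161-2180	PPIIARYIRLHPTHYSIRST	C1/C2
P2226-2245	KARLHLQGRSNAWRPQVNNP	C2
P2328-2347	HPQSWVHQIALRMEVLGCEA	C2
P1715-1734	RHYFIAAVERLWDYGMSSSP	A3
P1986-2005	KKEEYKMALYNLYPGVFETV	A3
P2068-2087	KLARLHYSGSINAWSTKEPF	C1
P2114-2133	SLYISQFIIMYSLDGKKWQT	C1
P2264-2283	TQGVKSLLTSMYVKEFLISS	C2
P2320-2339	LLTRYLRIHPQSWVHQIALR	C2
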