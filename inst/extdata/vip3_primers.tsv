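name	forward	reverse	start	end
screening	TGCCACTGGTATCAARGA	CCATTAATYGGAKTCAAAAATGTTTCACTGAT	78	1472
vip3Aa	ASTTTAAGATATGAGGYAACAGC	CATCGTAAAAATGTACAATAGGA	1297	2356
vip3Af	ASTTTAAGATATGAGGYAACAGC	TCAAATGATATATGACCACCA	1297	2348
vip3Ag	ASTTTAAGATATGAGGYAACAGC	ATGTAAAACGAGAAAGCTCTACA	1297	2323
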