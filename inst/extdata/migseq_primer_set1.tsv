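name	direction	full_seq	core	repeats	anchor	annealing_seq	set
(ACT)_4TG-f	forward	CGCTCTTCCGATCTCTGACTACTACTACTTG	ACT	4	TG	ACTACTACTACTTG	set-1
(ACT)_4TG-r	reverse	TGCTCTTCCGATCTGACACTACTACTACTTG	ACT	4	TG	ACTACTACTACTTG	set-1
(CTA)_4TG-f	forward	CGCTCTTCCGATCTCTGCTACTACTACTATG	CTA	4	TG	CTACTACTACTATG	set-1
(CTA)_4TG-r	reverse	TGCTCTTCCGATCTGACCTACTACTACTATG	CTA	4	TG	CTACTACTACTATG	set-1
(GTG)_4AC-f	forward	CGCTCTTCCGATCTCTGGTGGTGGTGGTGAC	GTG	4	AC	GTGGTGGTGGTGAC	set-1
(GTG)_4AC-r	reverse	TGCTCTTCCGATCTGACGTGGTGGTGGTGAC	GTG	4	AC	GTGGTGGTGGTGAC	set-1
(GT)_6TC-f	forward	CGCTCTTCCGATCTCTGGTGTGTGTGTGTTC	GT	6	TC	GTGTGTGTGTGTTC	set-1
(GT)_6TC-r	reverse	TGCTCTTCCGATCTGACGTGTGTGTGTGTTC	GT	6	TC	GTGTGTGTGTGTTC	set-1
(GTT)_4CC-f	forward	CGCTCTTCCGATCTCTGGTTGTTGTTGTTCC	GTT	4	CC	GTTGTTGTTGTTCC	set-1
(GTT)_4CC-r	reverse	TGCTCTTCCGATCTGACGTTGTTGTTGTTCC	GTT	4	CC	GTTGTTGTTGTTCC	set-1
(GTT)_4TC-f	forward	CGCTCTTCCGATCTCTGGTTGTTGTTGTTTC	GTT	4	TC	GTTGTTGTTGTTTC	set-1
(GTT)_4TC-r	reverse	TGCTCTTCCGATCTGACGTTGTTGTTGTTTC	GTT	4	TC	GTTGTTGTTGTTTC	set-1
(TG)_6AC-f	forward	CGCTCTTCCGATCTCTGTGTGTGTGTGTGAC	TG	6	AC	TGTGTGTGTGTGAC	set-1
(TG)_6AC-r	reverse	TGCTCTTCCGATCTGACTGTGTGTGTGTGAC	TG	6	AC	TGTGTGTGTGTGAC	set-1
(TTG)_4AC-f	forward	CGCTCTTCCGATCTCTGTTGTTGTTGTTGAC	TTG	4	AC	TTGTTGTTGTTGAC	set-1
(TTG)_4AC-r	reverse	TGCTCTTCCGATCTGACTTGTTGTTGTTGAC	TTG	4	AC	TTGTTGTTGTTGAC	set-1
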