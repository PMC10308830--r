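row	search	count	grand_total
top 10	ANST/POL	36128	413007
top 100	ANST/POL	140527	413007
top 200	ANST/POL	190759	413007
top 300	ANST/POL	222788	413007
top 500	ANST/POL	262875	413007
Lead	ANST/POL	6224	413007
Cadmium	ANST/POL	4692	413007
p,p'-DDT	ANST/POL	1571	413007
2,3,7,8-TCDD	ANST/POL	743	413007
top 10	BIOL/Occur	950454	9251975
top 100	BIOL/Occur	3303278	9251975
top 200	BIOL/Occur	4469288	9251975
top 300	BIOL/Occur	5214655	9251975
top 500	BIOL/Occur	6166490	9251975
Lead	BIOL/Occur	73043	9251975
Cadmium	BIOL/Occur	82544	9251975
p,p'-DDT	BIOL/Occur	15534	9251975
2,3,7,8-TCDD	BIOL/Occur	10066	9251975
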