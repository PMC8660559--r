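position,chrom,pos,ref,alt,delta,effect,aa_change,sift,gene
chr4B_17232065,chr4B,17232065,C,T,1.000,Intronic,,,TraesCS4B02G024000
chr6A_46782541,chr6A,46782541,G,A,0.851,Missense,R/C,0,TraesCS6A02G076600
chr6A_55741222,chr6A,55741222,G,A,0.888,Intronic,,,TraesCS6A02G087400
chr6A_57668862,chr6A,57668862,G,A,0.876,Missense,A/T,0,TraesCS6A02G099900
chr6A_67373891,chr6A,67373891,G,A,1.000,Missense,A/T,0,TraesCS6A02G099900
chr6A_76523438,chr6A,76523438,G,A,1.000,Intronic,,,TraesCS6A02G107700
chr6A_77099433,chr6A,77099433,G,A,1.000,Missense,T/I,0,TraesCS6A02G108300
chr6A_80699949,chr6A,80699949,G,A,1.000,Upstream,,,TraesCS6A02G111400
chr6A_84072498,chr6A,84072498,G,A,1.000,Intronic,,,TraesCS6A02G114100
chr6A_93819244,chr6A,93819244,G,A,0.964,Missense,H/Y,1,TraesCS6A02G121600
chr6A_94068104,chr6A,94068104,G,A,0.933,Missense,G/S,0,TraesCS6A02G121900
chr6A_96601065,chr6A,96601065,G,A,0.943,Synonymous,A,,TraesCS6A02G123000
chr6A_98048315,chr6A,98048315,G,A,1.000,Missense,P/L,0,TraesCS6A02G124200
chr6A_104309957,chr6A,104309957,G,A,0.892,Intergenic,,,
chr6A_116709274,chr6A,116709274,G,A,0.915,Missense,A/T,0.02,TraesCS6A02G141800
chr6A_137292502,chr6A,137292502,G,A,0.923,Intergenic,,,
chr6A_214559812,chr6A,214559812,C,T,0.898,Missense,S/N,0,TraesCS6A02G184000
chr6A_297671234,chr6A,297671234,G,A,0.806,Missense,V/I,0.72,TraesCS6A02G197400
chr6A_371735058,chr6A,371735058,G,A,0.852,Synonymous,A,,TraesCS6A02G208100
chr6A_456779221,chr6A,456779221,G,A,0.885,Missense,A/V,0.51,TraesCS6A02G245500
chr6A_458220665,chr6A,458220665,G,A,0.893,Intronic,,,TraesCS6A02G247100
chr6A_459076102,chr6A,459076102,G,A,0.875,Missense,P/S,0.35,TraesCS6A02G247200
chr6A_479267518,chr6A,479267518,G,A,0.823,Missense,T/I,0,TraesCS6A02G257000
chr6A_504123510,chr6A,504123510,G,A,0.883,Intergenic,,,
chr6A_517559399,chr6A,517559399,G,A,0.879,Synonymous,R,,TraesCS6A02G285800
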