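position,chrom,pos,ref,alt,delta,effect,aa_change,sift,gene
chr2A_732959676,chr2A,732959676,C,T,1.000,Intergenic,,,
chr2D_15472677,chr2D,15472677,C,T,1.000,Missense,A/T,0.38,TraesCS2D02G042900
chr3A_8326626,chr3A,8326626,C,T,0.833,Intronic,,,TraesCS3A02G009200
chr3B_12565097,chr3B,12565097,C,T,0.875,Intergenic,,,
chr3D_588999854,chr3D,588999854,G,A,0.833,"Splice region, synonymous",,,TraesCS3D02G498000
chr6D_36628312,chr6D,36628312,G,A,0.909,3' UTR,,,TraesCS6D02G072100
chr6D_42295410,chr6D,42295410,C,T,1.000,Intergenic,,,
chr6D_50958137,chr6D,50958137,G,A,0.875,Downstream,,,TraesCS6D02G085600
chr6D_57044844,chr6D,57044844,C,T,1.000,Intergenic,,,
chr6D_60487321,chr6D,60487321,C,T,1.000,Missense,G/E,0,TraesCS6D02G096300
chr6D_65341694,chr6D,65341694,C,T,1.000,Missense,G/S,0.56,TraesCS6D02G101900
chr6D_72022762,chr6D,72022762,C,T,0.960,Intronic,,,TraesCS6D02G107900
chr6D_79076045,chr6D,79076045,G,A,0.909,Missense,A/T,0.32,TraesCS6D02G112400
chr6D_84222670,chr6D,84222670,G,A,0.929,Downstream,,,TraesCS6D02G119000
chr6D_86733052,chr6D,86733052,G,A,1.000,Intronic,,,TraesCS6D02G122300
chr6D_110872402,chr6D,110872402,G,A,0.756,Synonymous,,,TraesCS6D02G141300
chr6D_119464714,chr6D,119464714,G,A,0.755,Intergenic,,,
chr6D_139310981,chr6D,139310981,G,A,0.817,Intronic,,,TraesCS6D02G161000
chr6D_140102996,chr6D,140102996,G,A,0.833,Intronic,,,TraesCS6D02G161800
chr6D_148079666,chr6D,148079666,G,A,0.790,Missense,P/S,0.01,TraesCS6D02G166500
chr6D_264681596,chr6D,264681596,G,A,0.815,"Missense, splice region",G/D,0,TraesCS6D02G192000
chr6D_292379919,chr6D,292379919,G,A,0.941,Intronic,,,TraesCS6D02G206900
chr6D_352357451,chr6D,352357451,C,T,1.000,5' UTR,,,TraesCS6D02G248900
chr6D_363004043,chr6D,363004043,G,A,1.000,Synonymous,,,TraesCS6D02G256800
chr7D_8178083,chr7D,8178083,C,T,0.833,Synonymous,,,TraesCS7D02G018200
chr7D_583986610,chr7D,583986610,G,A,1.000,Intronic,,,TraesCS7D02G470700
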