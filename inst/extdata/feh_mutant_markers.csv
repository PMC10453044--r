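snp_index,name,chromosome,span_start,span_end,sites
76092,wsnp_CAP8_c6680_3136899,6A,"1,28,36,428","1,28,36,621","6A:12836428:A;6B:12901233:B"
3722,BobWhite_c5092_422,6A,"1,30,71,495","1,30,71,594","6A:13071495:A"
71378,Tdurum_contig42906_732,6A,"3,26,58,889","3,26,58,989","6A:32658889:A"
55811,RAC875_c25556_1250,6A,"3,26,60,703","3,26,60,803","6A:32660703:A;6B:57296208:B;6D:30282758:B"
1675,BobWhite_c23193_170,6A,"4,02,21,884","4,02,21,984","6A:40221884:A;6D:41002267:B"
41259,Kukri_c14765_1655,6A,"4,10,83,842","4,10,83,933","6A:41083842:A;6B:40788991:B"
3378,BobWhite_c44549_83,6A,"4,10,83,289","4,10,83,389","6A:41083289:A;6B:41120044:B"
10716,BS00074183_51,6B,"5,44,19,374","5,44,19,474","6B:54419374:B"
75083,tplb0055h14_483,6B,"5,92,95,396","5,92,95,496","6B:59295396:A;6A:59400123:B"
18485,D_GBQ4KXB01B5NHZ_336,6D,"2,86,82,554","2,86,82,785","6D:28682554:A;6A:28333456:B"
46499,Kukri_c5531_358,6D,"3,02,83,208","3,02,83,308","6D:30283208:A;6B:30283456:B"
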