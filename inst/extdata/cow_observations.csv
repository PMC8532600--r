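cow,total,removed,used,minutes_removed,minutes_used
1,59628,1892,57736,6.3,192
2,45927,3902,42025,13,140
3,34468,619,33849,2.1,113
4,30263,582,29681,1.9,99
5,39405,7794,31611,26,105
6,31758,3201,28557,10.7,95
7,40784,1200,39584,4,132
8,37047,2527,34520,8.4,115
9,45039,1680,43359,5.6,145
10,36894,1350,35544,4.5,118
11,52770,7759,45011,25.9,150
12,36917,1664,35253,5.5,118
Total,490900,34170,456730,113.9,1522
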