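#! FIELDS time s conformer
1 2.0721051633473371 0
2 1.6459148945016848 0
3 1.4114837827237483 0
4 1.1987640033904174 1
5 0.62092360591717677 1
6 0.39390716182528934 1
7 0.54377737594586406 1
8 0.32479683237402013 0
9 0.42629540839219332 0
10 0.44705522147685139 1
11 0.51511080353963645 1
12 0.70951774325475836 0
13 0.65371190671800694 1
14 0.36537757146814415 0
15 0.57592986017440206 1
16 0.48303975045004333 1
17 0.54755351986295275 0
18 0.7093295622206014 0
19 0.69230239016834727 1
20 0.36941969599070101 1
21 0.72385913119931911 0
22 0.34349078951413464 0
23 0.58743904016648829 1
24 0.35926183461634098 0
25 0.38715603209844507 0
26 0.34201701569879583 1
27 0.33251707325044716 1
28 0.4634034353992223 0
29 0.39268511411229096 0
30 0.34975593391845244 1
31 0.39964106943695776 0
32 0.41036606541973991 0
33 0.40270788711169719 0
34 0.65822167432399692 1
35 0.43424110899766033 1
36 0.40374375547734825 1
37 0.70203614298783434 1
38 0.27768298952397141 1
39 0.3696479527241362 1
40 0.60241990552489388 1
41 0.70724491386297927 0
42 0.59315264629559206 1
43 0.38174141646656023 1
44 0.30617076882511518 0
45 0.4208715821767634 1
46 0.49328643745668826 0
47 0.46416882860120767 1
48 0.54101937217077534 1
49 0.7377135163833225 1
50 0.41188774988103705 1
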