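#! FIELDS time s sigma height
2.5 1.4853265351908267 0.050000000000000003 0.29999999999999999
5 0.62092360591717677 0.050000000000000003 0.29999999999999999
7.5 0.55455680776112126 0.050000000000000003 0.29999999999999999
10 0.44705522147685139 0.050000000000000003 0.29999999999999999
12.5 0.60735035987385322 0.050000000000000003 0.29999999999999999
15 0.57592986017440206 0.050000000000000003 0.29999999999999999
17.5 0.58640657151698161 0.050000000000000003 0.29999999999999999
20 0.36941969599070101 0.050000000000000003 0.29999999999999999
22.5 0.52552852280930051 0.050000000000000003 0.29999999999999999
25 0.38715603209844507 0.050000000000000003 0.29999999999999999
27.5 0.2033733572517073 0.050000000000000003 0.29999999999999999
30 0.34975593391845244 0.050000000000000003 0.29999999999999999
32.5 0.38017440483907783 0.050000000000000003 0.29999999999999999
35 0.43424110899766033 0.050000000000000003 0.29999999999999999
37.5 0.45325879415267845 0.050000000000000003 0.29999999999999999
40 0.60241990552489388 0.050000000000000003 0.29999999999999999
42.5 0.47420674751146397 0.050000000000000003 0.29999999999999999
45 0.4208715821767634 0.050000000000000003 0.29999999999999999
47.5 0.58056173298408098 0.050000000000000003 0.29999999999999999
50 0.41188774988103705 0.050000000000000003 0.29999999999999999
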