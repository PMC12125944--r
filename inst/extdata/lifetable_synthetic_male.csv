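age,sex,q_annual
45,male,0.002375295163986
46,male,0.00256218493305236
47,male,0.00276769992253866
48,male,0.00299369630058842
49,male,0.00324221521893726
50,male,0.00351550124816592
51,male,0.00381602265018947
52,male,0.00414649367107958
53,male,0.00450989905556395
54,male,0.0049095210046127
55,male,0.0053489688195869
56,male,0.0058322115006891
57,male,0.00636361359413802
58,male,0.00694797461183166
59,male,0.00759057237952899
60,male,0.00829721070506161
61,male,0.00907427179710505
62,male,0.00992877390794457
63,male,0.0108684347208532
64,male,0.0119017410545832
65,male,0.0130380255145272
66,male,0.0142875507828469
67,male,0.0156616023088584
68,male,0.0171725902368365
69,male,0.0188341614918262
70,male,0.0206613230357987
71,male,0.022670577407374
72,male,0.0248800717692775
73,male,0.0273097618096959
74,male,0.0299815919778537
75,male,0.0329196936816615
76,male,0.0361506032375149
77,male,0.0397035015407206
78,male,0.0436104776212032
79,male,0.0479068184648717
80,male,0.0526313277182518
81,male,0.0578266761548565
82,male,0.0635397870686344
83,male,0.0698222600752878
84,male,0.076730837149145
85,male,0.084327915104733
86,male,0.092682109151679
87,male,0.101868872612845
88,male,0.111971178402865
89,male,0.123080268422052
90,male,0.135296477634044
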