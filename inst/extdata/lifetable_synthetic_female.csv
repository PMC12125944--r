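age,sex,q_annual
45,female,0.00179551653199567
46,female,0.00192462622637129
47,female,0.00206660284507408
48,female,0.00222272869105146
49,female,0.00239441386009453
50,female,0.00258320897652657
51,female,0.00279081919811563
52,female,0.00301911961670074
53,female,0.00327017219362684
54,female,0.00354624438294585
55,female,0.00384982961058456
56,female,0.00418366979444294
57,female,0.00455078010881973
58,female,0.00495447621683229
59,female,0.00539840421678825
60,female,0.00588657357297824
61,female,0.00642339332831378
62,female,0.00701371192587512
63,female,0.00766286099902908
64,female,0.00837670352561973
65,female,0.00916168678115073
66,female,0.0100249005692211
67,female,0.0109741412551397
68,female,0.012017982181056
69,female,0.0131658510985828
70,female,0.0144281153182653
71,female,0.015816175344948
72,female,0.0173425678447361
73,female,0.0190210788735263
74,female,0.0208668683897621
75,female,0.0228966071759898
76,female,0.025128627405858
77,female,0.0275830882164532
78,female,0.0302821577813842
79,female,0.0332502135290619
80,female,0.0365140623145036
81,female,0.0401031825332072
82,female,0.0440499903638167
83,female,0.0483901325442275
84,female,0.0531628083254225
85,female,0.0584111235108595
86,female,0.0641824797790181
87,female,0.0705290028053863
88,female,0.0775080130505937
89,female,0.0851825434667519
90,female,0.0936219087978149
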