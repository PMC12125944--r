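age,sex,q_annual
45,general,0.00205761842353308
46,general,0.00221284889234571
47,general,0.0023835494519609
48,general,0.00257126183391672
49,general,0.00277768141695125
50,general,0.00300467253930662
51,general,0.0032542853370397
52,general,0.00352877426041969
53,general,0.00383061843564853
54,general,0.00416254405580715
55,general,0.0045275490032578
56,general,0.00492892992588676
57,general,0.00537031201173437
58,general,0.00585568173093072
59,general,0.00638942284065506
60,general,0.00697635597830827
61,general,0.00762178220049556
62,general,0.0083315308610544
63,general,0.00911201226055183
64,general,0.00997027554277039
65,general,0.0109140723610916
66,general,0.0119519268897984
67,general,0.0130932128126235
68,general,0.014348237983889
69,general,0.0157283375268772
70,general,0.0172459762102796
71,general,0.018914861027365
72,general,0.0207500649946585
73,general,0.0227681632882554
74,general,0.024987382947324
75,general,0.0274277674968888
76,general,0.0301113579767306
77,general,0.0330623920114208
78,general,0.0363075227194463
79,general,0.0398760594385683
80,general,0.0438002324415933
81,general,0.0481154840334167
82,general,0.0528607886584622
83,general,0.0580790049096644
84,general,0.0638172626182619
85,general,0.0701273885205165
86,general,0.0770663743458916
87,general,0.0846968915543599
88,general,0.0930878573718439
89,general,0.102315057236101
90,general,0.112461829274849
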