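# Initial training sample archive: 30 MRG designs with calibrated pressure and expansion metrics
# columns: W1..W5,T,L in mm; P in MPa; DR_32ms/DR_42ms dogboning ratios; RER recoil fraction
W1,W2,W3,W4,W5,T,L,P,DR_32ms,DR_42ms,RER
0.309,0.2587,0.2703,0.2355,0.2935,0.1245,4.6935,2.0988,0.2495,0.2518,0.0177
0.3168,0.3013,0.3323,0.2819,0.2065,0.1323,5.6613,1.8081,0.0002,0.0002,0.0205
0.2781,0.3129,0.2316,0.2239,0.2258,0.1052,5.2742,1.7864,0.1537,0.1568,0.0205
0.3129,0.2858,0.2277,0.2781,0.2806,0.1284,5.9839,1.7864,0.2010,0.2037,0.0162
0.3245,0.3323,0.2897,0.2935,0.2226,0.1258,5.8548,1.8289,0.0624,0.0634,0.0186
0.3052,0.2548,0.309,0.3245,0.2871,0.1168,6.3065,1.9537,0.3058,0.3107,0.0152
0.2239,0.3206,0.2355,0.251,0.271,0.1206,6.2419,1.8800,0.1500,0.1529,0.0158
0.2703,0.2819,0.3129,0.3168,0.2839,0.1026,5.0161,1.8908,0.1663,0.1681,0.0172
0.2587,0.3168,0.3361,0.2394,0.2516,0.1219,5.7258,1.9655,0.0434,0.0431,0.0186
0.2626,0.3361,0.3206,0.2974,0.2742,0.1116,4.8871,1.9850,0.2191,0.2234,0.0191
0.3284,0.2394,0.2548,0.3013,0.2581,0.1335,4.629,1.0199,0.2831,0.2874,0.0211
0.251,0.3052,0.3013,0.2742,0.2903,0.1361,5.9194,1.8888,0.0917,0.0918,0.0185
0.2742,0.2974,0.2394,0.2316,0.2484,0.1348,5.3387,1.9205,0.0656,0.0672,0.0194
0.2548,0.2665,0.2239,0.309,0.2194,0.1194,5.1452,1.8079,0.1861,0.1895,0.0217
0.2897,0.2703,0.2665,0.2897,0.2968,0.1039,6.371,1.9168,0.2538,0.2578,0.0151
0.3361,0.3284,0.2587,0.2703,0.2452,0.1077,5.5323,1.8502,0.0013,0.0022,0.0188
0.2432,0.2781,0.3284,0.2548,0.2129,0.1232,5.5968,1.7848,0.0498,0.0501,0.0194
0.2858,0.309,0.2781,0.3206,0.2097,0.1065,6.1129,1.7848,0.0580,0.0578,0.0198
0.2355,0.2626,0.2742,0.2277,0.2161,0.1155,6.0484,1.7490,0.0114,0.0125,0.0172
0.2471,0.2277,0.2819,0.2665,0.2677,0.1103,5.4677,1.8854,0.0402,0.0398,0.0177
0.2935,0.2316,0.2858,0.2587,0.2032,0.1271,4.8226,1.8120,0.2824,0.2865,0.0233
0.2394,0.2742,0.251,0.3052,0.2774,0.1374,4.9516,2.0552,0.1545,0.1556,0.0135
0.2316,0.251,0.3168,0.3129,0.2355,0.1297,6.1774,1.8380,0.1293,0.1307,0.0187
0.2974,0.3245,0.2626,0.3361,0.2419,0.131,4.5645,1.9760,0.3568,0.3630,0.0219
0.2277,0.2935,0.2471,0.3323,0.2323,0.1142,5.2097,1.8269,0.1689,0.1720,0.0204
0.3323,0.2897,0.3245,0.2626,0.2613,0.1129,4.7581,1.9655,0.2288,0.2322,0.0193
0.2819,0.2471,0.3052,0.2432,0.2548,0.1013,6.4355,1.7955,0.1695,0.1732,0.0166
0.2665,0.2239,0.2974,0.3284,0.2387,0.1181,5.7903,1.8350,0.0500,0.0515,0.0182
0.3013,0.2432,0.2935,0.2471,0.2645,0.1387,5.4032,2.0010,0.0348,0.0352,0.0182
0.3206,0.2355,0.2432,0.2858,0.229,0.109,5.0806,1.8160,0.1674,0.1697,0.0202
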