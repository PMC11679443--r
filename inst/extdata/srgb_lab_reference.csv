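R,G,B,L,a,b
74,190,79,68.639169,-54.846140,45.711961
65,122,13,45.732009,-36.413898,47.370801
110,86,11,37.834281,2.567274,42.551062
97,161,180,62.780550,-15.374429,-16.226080
188,133,82,59.959133,15.467643,35.649139
210,144,37,64.791658,16.474736,61.825392
239,50,26,52.633372,69.012412,57.722377
236,175,170,76.919523,21.570656,11.309829
82,94,72,38.317559,-9.208454,11.105533
2,84,202,38.925420,26.372655,-66.659394
242,78,61,56.751285,61.699982,45.088352
152,180,191,71.608078,-7.123635,-8.765275
237,139,199,69.892286,45.078349,-14.948038
87,66,172,35.791826,36.486327,-53.984640
147,180,250,73.379744,6.171779,-38.235665
215,128,232,66.300105,49.707056,-38.998186
123,12,40,25.648790,45.674669,15.398471
249,130,48,66.766853,40.274375,61.449534
204,104,180,58.070830,49.361461,-22.565299
146,173,14,66.542989,-27.602463,66.403395
166,162,219,68.795567,13.603829,-28.329613
232,185,99,77.731892,7.221535,49.455861
128,57,232,43.271896,64.558571,-76.442259
245,165,228,77.237019,38.887446,-19.695296
146,250,44,89.234524,-59.634244,79.674412
244,137,197,70.287405,48.064545,-13.154766
167,138,204,62.297665,24.008046,-30.016831
216,61,154,52.144699,67.437200,-16.293035
189,145,162,64.707459,19.274496,-2.509193
13,236,220,84.606348,-49.595488,-5.504612
242,137,204,70.268047,48.471617,-17.099932
95,221,221,81.490135,-34.541748,-10.519883
127,42,84,31.368513,40.816651,-5.806805
210,164,112,70.472660,10.453732,33.413813
241,39,61,52.392038,73.056443,40.249213
47,133,8,48.755398,-46.238809,50.699433
185,209,201,81.909530,-9.582876,1.241899
37,197,196,72.433571,-38.164939,-10.713688
26,14,201,26.007298,63.487890,-87.405959
229,180,45,75.757409,5.714876,69.657374
41,93,179,40.496864,13.842502,-50.659179
125,115,115,49.325233,3.857254,1.398060
202,119,13,57.830222,26.048535,62.378197
44,5,128,16.513652,47.048734,-58.717006
38,152,48,55.155398,-52.026736,44.162914
213,34,24,46.124414,65.629921,51.465769
107,76,245,45.476529,55.898181,-80.239296
25,198,32,69.963033,-68.958658,64.020514
255,81,15,59.146193,63.684066,66.780125
43,78,136,33.433400,7.522797,-36.166632
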