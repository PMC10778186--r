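L1,a1,b1,L2,a2,b2,de2000
30.672436,55.681159,71.365989,19.421884,26.185485,-12.004582,37.35084926
5.093207,44.106296,-0.978619,60.779752,39.892714,-38.710404,48.15069248
15.855709,-26.506106,28.864970,18.344505,-32.379376,64.164614,12.00140473
16.821065,-6.141756,67.325007,29.821160,59.460093,15.453117,52.60610442
31.695366,-52.319852,4.664783,49.929247,31.595552,-20.158809,50.41857781
35.454912,-6.614893,-42.015431,59.286658,73.884938,70.281684,58.10936842
39.487262,-17.357842,53.254980,32.968597,22.040820,19.108044,34.46984437
4.131747,-24.034322,41.432845,50.958543,-68.968188,-73.401782,63.28393913
11.668984,0.521478,-46.335325,88.023117,59.364919,14.235261,88.58450887
21.664049,36.397210,43.559617,75.913349,-30.439636,72.467584,69.65401539
22.174340,75.997871,-33.082775,23.444531,-17.076184,26.227239,64.22928779
59.443017,-18.305128,23.866176,7.803338,-13.327654,-13.805256,49.46079013
20.638876,66.737995,-6.360443,28.557715,53.624593,62.706523,34.38802284
66.983457,-73.026010,61.308277,0.449876,-46.602892,41.640430,54.33949261
21.705609,46.033061,60.376232,2.827409,-43.263181,3.816081,56.06473924
4.812121,-3.165476,-75.043209,91.730768,-1.552971,-26.573342,87.30669220
31.822068,-28.242355,8.413464,13.805585,-26.341139,-2.802827,14.92147497
49.755746,29.651610,69.160486,4.347713,-54.466090,23.459949,59.66573920
7.031637,75.517382,-30.440429,32.475175,-61.803430,-27.905763,76.79188555
77.289429,-19.167837,78.947885,92.875760,-60.713251,-67.596493,61.31166145
46.173170,34.304361,77.539946,3.971593,54.279430,66.996941,33.31024578
85.311369,-79.684277,-17.482124,49.218514,29.093946,34.622338,63.60164962
68.436519,35.239586,0.881030,3.133264,-30.891728,28.728922,76.34875817
5.195415,71.154276,37.609709,99.852008,8.924400,76.494817,101.99625272
72.095497,16.157376,26.503611,88.758124,-55.630109,-61.185056,49.77590138
55.671452,45.241263,-13.093977,83.975034,19.147013,-13.430978,24.64333021
84.011666,-59.565756,10.799206,37.925072,4.870199,-73.924396,58.64476445
11.788364,-41.367911,-10.295188,9.696237,-11.061523,0.391096,15.52433053
23.943014,-1.424871,42.668452,7.339125,-23.024012,-40.237809,49.27000398
94.405647,35.898351,-25.178651,33.640868,-49.164146,14.565539,68.43637591
23.078139,-1.725500,-14.616003,58.567618,-21.842507,61.988192,53.10427552
85.397057,14.289547,-33.325075,93.766299,-62.414845,29.307568,44.52389614
65.927377,56.438310,-41.057767,2.596254,-77.095020,-22.151851,81.42452353
23.679114,-5.814911,61.691696,23.914775,69.579186,43.533688,45.61398033
8.114314,-58.628512,-33.645303,2.493660,26.654005,12.931191,74.72548566
85.552177,-65.299418,-73.387859,84.260055,72.303029,-10.114892,105.45833930
30.552570,71.633954,9.755824,74.121414,32.281843,-4.971575,44.98528361
64.660139,49.589320,1.976624,77.871016,24.717424,-4.504983,14.30928369
9.848620,44.026115,-45.877432,95.198693,77.638646,30.993097,89.61204223
90.305635,-27.095189,4.726699,90.047570,23.979033,45.591676,39.24251144
65.869682,-5.532690,-60.303093,39.953005,30.361246,-49.743975,37.64459388
40.218337,-59.799712,52.739164,10.371228,-35.370866,-61.072688,60.45026755
67.876068,40.035021,-4.065395,78.259650,2.911905,36.889390,39.96936551
51.938699,45.558381,12.950879,15.349065,18.407954,47.800620,41.51749056
45.981758,-50.501776,-40.585589,38.219121,39.963140,24.297354,76.58889418
58.570412,-12.295720,-56.256195,73.309924,-30.893918,-77.261590,15.24479419
62.678003,20.084324,-17.021671,68.621912,67.185281,-8.843887,18.59373650
8.545885,-10.128344,37.392064,58.875967,-71.293207,-12.602961,53.42263888
75.554008,60.389457,34.947599,45.610466,21.793608,-32.512703,42.82999824
6.613880,-65.747347,-32.074827,55.107614,-16.578078,-77.232710,44.75972174
72.225007,-7.298533,-35.659142,63.257528,-0.716643,-36.062526,8.44970663
48.499544,-78.664916,-45.546891,27.346463,68.919668,56.814750,71.44892259
22.798225,-77.314424,30.791650,62.000108,-28.359149,-47.611295,56.24539257
19.111457,-15.401327,48.890938,58.092825,75.376675,-69.786125,81.89765958
62.090740,20.825852,59.091474,59.119627,-50.033244,-55.247937,55.60652062
69.589927,-78.874437,-47.959417,54.629015,30.433269,-62.488734,46.92772604
18.361263,16.283583,73.945219,69.536558,48.855632,1.875289,65.74119420
70.275710,-32.880978,-62.071933,15.627009,-11.767021,7.232260,60.74384139
22.430903,6.422126,-25.478262,26.548230,46.709425,-34.640153,20.07622431
35.198570,18.875665,26.948111,64.510622,-72.281411,6.509091,57.09378174
99.848199,-36.760160,43.337926,9.044740,32.750510,-54.191452,102.30794466
39.063255,24.243315,60.265220,48.021882,40.618288,59.278509,12.47785726
35.034442,-9.075519,-17.782059,21.602694,-37.236977,40.866236,39.34218196
62.317426,59.094601,-79.866172,46.701523,-46.509178,61.460931,64.43602970
44.611482,20.228199,58.523211,47.371831,57.800520,-46.243803,54.26895657
34.737828,-2.961679,-6.817253,96.595740,51.598518,-61.050844,52.11015452
58.080280,36.753856,-61.870417,69.870752,-39.392006,-32.338288,37.79525956
12.538234,-47.965499,21.006770,77.794957,-21.179820,-69.054063,76.83167481
12.127544,51.544779,60.896406,76.802585,-50.093496,-69.158135,93.81064357
64.614101,62.931674,74.808141,88.830999,3.007865,-1.285816,35.67033600
60.926469,-11.068066,30.883141,49.251076,20.353775,-4.974272,40.10307244
94.143266,27.898627,-50.441453,4.425448,2.174510,-11.617518,90.73584882
90.529271,18.073236,-56.219719,92.506283,-54.807042,18.768872,45.23046443
0.416406,-68.271968,-36.214203,45.997583,-48.883356,-78.752943,36.18271625
62.476696,-26.486230,74.966358,7.069068,-12.234006,-53.566971,79.32684864
70.912939,-40.440721,52.702776,88.683871,64.524889,-19.078114,78.90574527
27.096790,-2.929976,-66.673312,63.615405,-44.699215,3.320536,50.01324756
60.425943,57.145907,-62.124501,90.153109,44.481609,-70.821416,23.28118352
14.734709,51.624540,-41.341745,44.684892,59.289701,28.259137,37.29988237
15.624691,-10.448945,13.566389,41.151025,-20.753865,76.666331,28.80283901
16.451279,-20.503476,-76.543709,75.654553,-57.516111,-56.893467,58.83958457
9.206459,73.729368,-17.835561,32.163312,52.239116,36.199922,30.71942421
97.758356,43.820192,8.123696,36.587241,75.766252,73.058265,54.77243758
7.758747,-47.170046,-33.718923,12.944331,13.424801,0.963820,58.45864679
59.343243,-78.543138,-3.626637,0.596689,31.146639,-28.758565,69.05993692
47.604251,-24.267198,45.573223,81.528907,78.648218,-46.442993,81.76256707
36.828235,62.805621,-49.612674,57.903653,-23.474029,-47.477623,56.47981101
2.340428,63.299514,27.366926,0.687841,79.060765,-59.893184,30.69790866
33.196570,15.288605,-33.730252,39.028011,-32.323266,38.280905,47.20513099
28.609178,12.900564,-14.970793,45.427474,-51.822738,61.492185,57.12814879
54.068431,-58.449408,72.201202,47.487435,-65.066281,-65.577382,57.80952210
10.931960,70.935821,79.354919,5.719010,79.252613,37.770006,18.97986952
71.585757,-1.776613,-38.622880,19.513435,40.806005,50.114012,67.71871910
22.089181,-25.263500,78.289954,96.280495,35.888714,-41.551587,97.64081274
39.063398,41.159227,-28.794296,61.717879,-75.119782,-45.372725,72.82980748
84.851888,13.636040,-24.146255,90.414763,35.856576,-39.448134,10.51646833
47.603760,11.516303,37.675439,47.526255,51.896972,-45.877228,48.52170675
44.215648,8.716767,-32.430234,3.234672,-73.968822,-31.529121,46.02869648
91.423985,-78.799698,-61.387308,5.214905,-9.036468,-52.453566,88.44212522
67.148390,-36.748637,43.220773,25.883989,-36.193321,-22.463524,53.55558281
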