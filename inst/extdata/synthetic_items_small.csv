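"subject_id","group","sex","education","age","memory","fluency","language","visuospatial","orientation","hd1","hd2","hd3","hd4","hd5","hd6","hd7","ha1","ha2","ha3","ha4","ha5","ha6","ha7","ace_r_total"
"young_00001","young",0,3,29.7,0.8142,0.7877,0.9493,0.9903,0.9433,0,0,0,0,1,0,0,1,0,1,3,0,0,0,0.8969
"young_00002","young",0,2,37.9,0.4555,0.6026,0.9055,0.9878,0.9895,0,1,3,0,0,0,0,1,1,0,0,0,0,1,0.7882
"young_00003","young",0,3,26.3,0.937,0.9078,0.8673,0.9885,0.9599,0,0,2,0,0,0,0,0,0,0,0,0,0,0,0.9321
"young_00004","young",1,3,26.6,0.8123,0.614,0.9059,0.9502,0.9251,0,3,1,0,3,0,1,0,0,0,0,0,0,0,0.8415
"young_00005","young",0,3,42.6,0.8806,0.9664,0.9769,0.9732,0.9487,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0.9491
"young_00006","young",0,3,26,0.9238,0.9098,0.9587,0.9709,0.97,0,0,0,0,2,0,0,2,2,2,0,0,3,0,0.9467
"young_00007","young",0,3,29.2,0.9686,0.9372,0.9155,0.9402,0.9763,0,0,0,0,0,0,0,1,0,1,0,0,1,2,0.9476
"young_00008","young",0,3,26.5,0.4776,0.2249,0.6715,0.9446,0.9634,0,1,3,1,0,1,0,0,0,0,0,0,0,0,0.6564
"young_00009","young",0,3,24.1,0.9626,0.9943,0.9844,0.9932,0.9841,0,0,0,0,0,0,0,2,0,0,0,0,0,1,0.9837
"young_00010","young",0,2,36,0.9938,0.9619,0.9843,0.9797,0.9764,0,0,0,0,1,0,1,0,2,2,1,0,0,0,0.9792
"young_00011","young",0,0,27.6,0.957,0.9806,0.977,0.9819,0.9847,0,0,0,0,0,0,0,0,0,1,1,0,2,0,0.9762
"young_00012","young",0,3,28.4,0.8848,0.8082,0.9527,0.9738,0.9686,0,1,0,0,2,0,0,0,0,2,0,0,0,0,0.9176
"young_00013","young",0,3,41.7,0.4141,0.4881,0.7375,0.9577,0.9554,0,1,2,2,1,0,0,0,0,0,0,0,0,0,0.7105
"young_00014","young",0,2,31.7,0.7827,0.8763,0.9299,0.9918,0.9698,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.9101
"young_00015","young",1,3,40.6,0.9814,0.9856,0.9575,0.9831,0.9663,0,2,0,0,0,0,0,0,0,2,2,0,0,0,0.9748
"young_00016","young",1,3,36,0.9287,0.8515,0.9382,0.9713,0.9716,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.9323
"young_00017","young",1,3,28.7,0.9662,0.8918,0.9507,0.9694,0.9048,0,0,0,0,0,0,0,0,0,2,1,0,1,0,0.9366
"young_00018","young",0,3,43.2,0.9583,0.983,0.9784,0.9832,0.9804,0,0,0,0,0,0,0,0,0,1,0,0,0,1,0.9767
"young_00019","young",1,3,36.8,0.8478,0.8898,0.9255,0.9818,0.9904,2,0,3,2,0,0,0,0,0,0,0,0,1,0,0.927
"young_00020","young",1,3,39.6,0.931,0.7883,0.947,0.978,0.8986,0,0,1,2,2,3,3,0,1,0,0,0,0,0,0.9086
"young_00021","young",0,3,30.4,0.6596,0.6378,0.9052,0.9581,0.9269,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0.8175
"young_00022","young",0,3,31.7,0.9302,0.8995,0.9289,0.9479,0.9859,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.9385
"young_00023","young",0,3,33.9,0.9872,0.9622,0.9809,0.9853,0.9714,0,0,0,0,0,0,0,0,0,3,1,0,2,2,0.9774
"young_00024","young",0,3,27.5,0.9806,0.9757,0.9877,0.9945,0.9756,0,0,0,0,1,1,0,0,0,0,0,0,0,0,0.9828
"young_00025","young",1,3,43.3,0.9349,0.9027,0.9569,0.9883,0.9547,1,1,0,0,1,1,3,1,2,0,1,2,0,2,0.9475
"old_00001","old",0,0,69.6,0.9209,0.7406,0.9647,0.9847,0.8394,0,0,1,0,0,0,0,0,1,0,0,0,0,0,0.8901
"old_00002","old",1,0,74.3,0.893,0.8062,0.9438,0.905,0.9206,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0.8937
"old_00003","old",1,3,70.4,0.2959,0.5565,0.7901,0.7598,0.8003,2,0,1,0,0,0,2,1,0,0,0,2,3,2,0.6405
"old_00004","old",1,3,78.5,0.8512,0.5726,0.833,0.8655,0.9315,0,1,1,0,0,0,1,0,0,0,0,0,0,0,0.8108
"old_00005","old",1,3,75,0.9567,0.9812,0.9845,0.9087,0.7923,1,0,0,1,0,0,0,1,0,1,3,2,0,0,0.9247
"old_00006","old",1,0,74.5,0.5562,0.2383,0.8652,0.8637,0.8191,0,0,0,0,1,3,3,0,0,0,0,0,0,0,0.6685
"old_00007","old",0,3,85.3,0.8034,0.7435,0.9355,0.9551,0.9471,0,1,0,1,1,0,0,1,1,0,0,0,0,0,0.8769
"old_00008","old",0,0,79.5,0.9177,0.9094,0.933,0.8749,0.945,0,0,0,0,0,0,0,0,0,1,2,1,3,1,0.916
"old_00009","old",0,3,80,0.4177,0.6098,0.8702,0.9648,0.8795,0,0,0,0,0,1,0,1,1,0,0,0,0,1,0.7484
"old_00010","old",1,1,66.6,0.5696,0.3346,0.3769,0.7932,0.8958,0,2,1,2,3,2,3,0,0,0,0,2,1,1,0.594
"old_00011","old",0,3,83,0.9777,0.9058,0.9233,0.8959,0.9697,2,0,0,0,0,0,0,0,0,0,0,0,0,0,0.9345
"old_00012","old",1,0,77.6,0.7846,0.6614,0.8691,0.8412,0.9086,1,1,0,0,1,0,0,1,0,0,0,0,0,0,0.813
"old_00013","old",0,0,87.7,0.9611,0.907,0.9908,0.9727,0.9207,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0.9505
"old_00014","old",0,3,75.7,0.8674,0.8202,0.9216,0.9344,0.9706,1,0,0,0,1,0,0,0,0,1,2,0,0,0,0.9028
"old_00015","old",0,3,67.8,0.6196,0.6766,0.8703,0.8755,0.9266,0,0,1,0,2,0,2,0,0,0,0,0,0,1,0.7937
"old_00016","old",0,3,81.3,0.7214,0.8722,0.9223,0.6761,0.9315,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0.8247
"old_00017","old",0,3,70.9,0.904,0.82,0.9327,0.7622,0.8358,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0.8509
"old_00018","old",1,0,78.5,0.8358,0.8164,0.8294,0.8811,0.8715,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0.8469
"old_00019","old",0,3,82.3,0.5189,0.2436,0.593,0.835,0.9764,0,0,0,0,2,3,2,0,0,0,1,0,0,0,0.6334
"old_00020","old",0,3,72.6,0.8447,0.8297,0.9673,0.8694,0.8567,0,0,0,0,0,0,0,0,0,0,2,1,0,0,0.8736
"old_00021","old",1,3,85.8,0.7636,0.7862,0.8992,0.889,0.8485,0,0,0,0,0,1,0,1,1,0,0,0,0,0,0.8373
"old_00022","old",1,3,78.2,0.4703,0.6983,0.8422,0.8839,0.9157,0,0,0,0,1,0,2,0,0,0,0,0,0,0,0.7621
"old_00023","old",1,3,77,0.7058,0.6411,0.8176,0.8175,0.9221,0,0,0,0,0,0,0,1,0,0,1,0,0,0,0.7808
"old_00024","old",0,1,85.7,0.8448,0.8006,0.9107,0.7815,0.8491,0,0,0,0,0,0,0,0,0,2,2,3,3,0,0.8373
"old_00025","old",0,3,81.8,0.536,0.5876,0.9135,0.838,0.9099,2,1,0,0,1,0,0,2,0,0,0,0,0,0,0.757
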