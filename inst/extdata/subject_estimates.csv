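subject_id,dlpfc_self,str_to_dlpfc,dlpfc_to_str,str_self
1,6.663,0.856,0.848,7.744
2,2.527,0.846,0.769,7.297
3,6.91,0.857,0.852,7.5
4,3.664,0.831,0.762,7.715
5,2.483,0.85,0.771,8.438
6,1.899,0.869,0.78,8.414
7,2.172,0.856,0.764,8.703
8,1.283,0.908,0.815,8.24
9,6.897,0.855,0.858,6.773
10,7.499,0.856,0.855,7.594
11,3.819,0.831,0.772,7.336
12,7.461,0.849,0.854,6.845
13,3.102,0.844,0.766,7.576
14,7.066,0.855,0.858,6.916
15,7.518,0.839,0.852,6.215
16,5.636,0.853,0.832,7.724
17,2.681,0.818,0.757,6.391
18,2.217,0.82,0.718,8.018
19,5.615,0.847,0.822,7.787
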