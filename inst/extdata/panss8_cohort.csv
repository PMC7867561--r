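subject_id,p1,p2,p3,n1,n4,n6,g5,g9,medication,dup_months,printed_negative,printed_positive,printed_total
1,4,4,4,4,5,3,2,4,0,24,12,12,30
2,5,4,5,2,3,1,3,4,0,4,6,14,27
3,4,5,4,5,4,3,1,3,1,1,12,13,29
4,5,1,5,3,4,3,1,4,0,2,10,11,26
5,5,3,4,2,3,3,1,3,1,2,8,12,24
6,5,1,5,3,5,3,3,2,0,9,11,11,27
7,6,5,6,1,1,1,4,5,0,12,3,17,29
8,5,4,4,2,4,2,1,4,0,1,8,13,26
9,7,3,5,4,3,1,2,6,1,59,8,15,31
10,6,4,2,1,1,1,1,3,0,3,3,12,19
11,6,3,2,1,1,1,1,4,0,14,3,11,19
12,4,2,5,3,1,2,1,3,1,NA,6,11,21
13,5,6,5,1,3,4,3,5,0,6,8,16,32
14,5,4,2,1,1,1,1,5,1,1,3,11,20
15,7,4,6,1,1,1,1,6,0,NA,3,17,27
16,5,1,5,4,3,1,1,3,0,9,8,11,23
17,7,3,2,5,4,3,1,3,0,72,12,12,28
18,5,1,5,1,5,1,1,3,1,1,7,11,22
19,5,3,1,3,3,3,1,4,1,1,9,9,23
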