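patient_id,age,who,gleason,psa_before,psa_after,n_cycles
1,73,2,9,560,>1200,1
2,61,1,7,385,28.1,6
3,64,0,8,68,915.1,3
4,50,1,8,68.4,1636,4
5,78,0,7,14.2,1.52,6
6,83,1,6,46.79,5.88,6
7,79,1,6,47,52,4
8,75,1,10,22.4,376,5
10,85,1,7,92.77,15.86,2
11,68,1,7,37,13.87,6
12,73,1,7,0.8,0.12,5
15,75,1,8,198.4,152,2
16,77,1,7,87.31,7,6
19,79,1,7,51.7,158.1,5
20,63,1,9,21.99,3.8,6
21,83,1,8,65.263,0.4,6
22,73,2,8,27.11,<0.006,6
23,80,2,8,98.42,3.82,6
24,75,1,9,134.59,243.82,4
28,60,1,9,172.68,243,1
30,64,1,7,19.3,35.42,6
31,74,0,7,77.28,2,6
32,70,0,NA,42.55,1.49,6
33,78,1,8,93.3,179,6
36,63,1,9,2009,>5000,3
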