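subArea,rowNum,cropNum,manual,computed,xGroup
A1,58,3,0.510,0.651,0<=x<5
A1,48,4,0.530,0.628,0<=x<5
A1,52,4,0.600,0.333,0<=x<5
A1,56,4,0.580,0.308,0<=x<5
A1,55,5,0.600,0.581,0<=x<5
A1,51,7,0.600,0.415,0<=x<5
A1,57,7,0.600,0.507,0<=x<5
A1,47,9,0.500,0.309,0<=x<5
A1,49,13,0.500,0.313,5<=x<8
A1,53,15,0.510,0.590,5<=x<8
A1,50,19,0.600,0.328,5<=x<8
B1,17,1,0.510,0.503,0<=x<5
B1,36,2,0.520,0.609,0<=x<5
B1,21,3,0.550,0.495,0<=x<5
B1,15,5,0.560,0.621,0<=x<5
B1,32,6,0.560,0.572,0<=x<5
B1,16,7,0.560,0.593,0<=x<5
B1,37,8,0.520,0.611,0<=x<5
B1,29,10,0.560,0.616,0<=x<5
B1,43,11,0.530,0.673,5<=x<8
B1,33,12,0.560,0.312,5<=x<8
B1,23,13,0.620,0.408,5<=x<8
B1,34,14,0.540,0.477,5<=x<8
B1,44,15,0.550,0.613,5<=x<8
B1,24,16,0.560,0.337,5<=x<8
B1,40,18,0.440,0.594,5<=x<8
B1,45,21,0.560,0.561,x>=8
B1,28,23,0.500,0.682,x>=8
C1,12,3,0.450,0.542,0<=x<5
C1,13,6,0.510,0.573,0<=x<5
C1,9,7,0.400,0.521,0<=x<5
C1,14,8,0.560,0.575,0<=x<5
C1,10,9,0.400,0.542,0<=x<5
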