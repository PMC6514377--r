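parcel,plot,NLV,DNL,DTD_ms
1,4,4,3,401
1,7,4,3,656
1,10,4,3,1566
1,13,5,4,2691
1,16,5,4,954
1,19,6,4,401
1,22,8,6,386
1,25,5,4,1188
1,28,5,5,513
1,31,5,4,1156
2,3,5,3,435
2,6,5,4,649
2,9,5,4,414
2,12,6,4,597
2,15,4,3,898
2,18,5,4,752
2,21,5,3,425
2,24,4,3,398
2,27,4,3,477
2,30,3,3,674
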