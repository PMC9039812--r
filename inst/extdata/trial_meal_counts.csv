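apartment_id,preference,activity,observed,normal,anomaly
1,NP,6:00-9:00,69,56,13
1,NP,11:00-13:00,66,63,3
2,N,7:00-9:00,51,49,2
3,N,7:00-10:00,60,58,2
4,N,6:00-7:00,56,56,0
4,N,11:00-13:00,42,40,2
4,N,16:00-18:00,46,46,0
5,N,5:00-8:00,46,46,0
6,NP,7:00-10:00,52,51,1
8,NP,7:00-10:00,62,51,11
8,NP,10:00-13:00,64,60,4
8,NP,17:00-20:00,57,52,5
9,N,8:00-10:00,45,40,5
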