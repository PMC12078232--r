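station_label,n_events,mean_actual_over_idea,min_actual_over_idea,max_actual_over_idea,n_gtv_affected,n_ctv_minus_gtv
1R,3,0.426,0,0.85,0,3
1L,2,0,0,0,0,2
2R,8,0.197,0,0.70,0,8
2L,0,NA,NA,NA,0,0
3A,3,0.030,0.01,0.09,0,3
3P,0,NA,NA,NA,0,0
4R,24,0.476,0,0.94,10,14
4L,3,0.463,0,0.98,2,1
5,3,0.908,0.73,1,2,1
6,10,0.114,0,0.57,1,9
7,18,0.559,0,0.90,8,10
8,2,0.551,0,0.87,0,2
10R,50,0.715,0,1,50,0
10L,23,0.651,0,1,23,0
11R,11,0.593,0,1,5,6
11L,10,0.641,0.15,0.82,4,6
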