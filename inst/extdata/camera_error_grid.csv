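height_m,distance_m,model,A,B,broken
0.5,1.5,SMPL,0.223,0.326,FALSE
1.0,1.5,SMPL,0.251,0.284,FALSE
1.5,1.5,SMPL,0.204,0.274,FALSE
0.5,2.0,SMPL,0.25,0.124,FALSE
1.0,2.0,SMPL,0.197,0.14,FALSE
1.5,2.0,SMPL,0.257,0.29,FALSE
0.5,2.5,SMPL,0.114,0.157,FALSE
1.0,2.5,SMPL,0.188,0.237,FALSE
1.5,2.5,SMPL,0.192,0.16,FALSE
0.5,3.0,SMPL,0.081,0.074,FALSE
1.0,3.0,SMPL,0.063,0.057,FALSE
1.5,3.0,SMPL,0.115,0.047,FALSE
0.5,3.5,SMPL,0.125,0.155,FALSE
1.0,3.5,SMPL,0.245,0.156,FALSE
1.5,3.5,SMPL,0.162,0.122,FALSE
0.5,4.0,SMPL,0.224,0.172,FALSE
1.0,4.0,SMPL,0.12,0.149,FALSE
1.5,4.0,SMPL,0.092,0.157,FALSE
0.5,1.5,PIFuHD,0.174,0.21,FALSE
1.0,1.5,PIFuHD,0.186,0.24,FALSE
1.5,1.5,PIFuHD,0.155,0.232,FALSE
0.5,2.0,PIFuHD,0.142,0.129,FALSE
1.0,2.0,PIFuHD,0.127,0.146,FALSE
1.5,2.0,PIFuHD,0.115,0.178,FALSE
0.5,2.5,PIFuHD,0.07,0.184,FALSE
1.0,2.5,PIFuHD,0.034,0.24,FALSE
1.5,2.5,PIFuHD,0.094,0.153,FALSE
0.5,3.0,PIFuHD,0.058,0.074,FALSE
1.0,3.0,PIFuHD,0.021,0.034,FALSE
1.5,3.0,PIFuHD,0.045,0.041,FALSE
0.5,3.5,PIFuHD,0.065,0.081,FALSE
1.0,3.5,PIFuHD,0.242,0.213,FALSE
1.5,3.5,PIFuHD,0.172,0.084,FALSE
0.5,4.0,PIFuHD,NA,NA,TRUE
1.0,4.0,PIFuHD,NA,NA,TRUE
1.5,4.0,PIFuHD,NA,NA,TRUE
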