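r,g,b,L,a,b_lab
0,0,0,0.000000,0.000000,0.000000
0,0,128,12.971164,47.501124,-64.700446
0,0,255,32.295673,79.185591,-107.857300
0,128,0,46.227658,-51.698683,49.897076
0,128,128,48.254142,-28.848145,-8.473973
0,128,255,54.714539,18.773464,-70.913764
0,255,0,87.735099,-86.183030,83.179703
0,255,128,88.482921,-76.750857,46.576784
0,255,255,91.113301,-48.090596,-14.126330
128,0,0,25.535407,48.045037,38.057105
128,0,128,29.784243,58.927141,-36.484751
128,0,255,40.908726,83.166511,-93.286611
128,128,0,51.869087,-12.930024,56.674667
128,128,128,53.585013,-0.001473,0.002791
128,128,255,59.200517,33.092555,-63.453800
128,255,0,89.908871,-67.786250,85.823721
128,255,128,90.626619,-59.894205,49.702313
128,255,255,93.155941,-35.233958,-10.862816
255,0,0,53.240588,80.092308,67.202751
255,0,128,54.891564,84.534269,4.081436
255,0,255,60.323507,98.233054,-60.821015
255,128,0,67.054801,42.825382,74.017459
255,128,128,68.213583,48.187830,22.698332
255,128,255,72.175983,64.933657,-42.072886
255,255,0,97.139507,-21.554681,94.478122
255,255,128,97.769206,-16.539492,59.984462
255,255,255,100.000000,-0.002455,0.004653
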