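parameter,group,n,mean,sd
RALD,IHD,91,112.482,14.686
RALD,MA,29,114.503,15.470
RALD,control,66,118.845,12.498
RAOD,IHD,91,145.278,17.029
RAOD,MA,29,148.907,18.682
RAOD,control,66,153.055,13.801
RVLD,IHD,91,153.321,19.312
RVLD,MA,29,156.786,18.270
RVLD,control,66,153.071,19.981
RVOD,IHD,91,184.368,23.590
RVOD,MA,29,186.334,20.974
RVOD,control,66,182.414,21.803
AVR,IHD,91,0.798,0.122
AVR,MA,29,0.803,0.093
AVR,control,66,0.850,0.122
AWT,IHD,91,16.398,2.936
AWT,MA,29,17.202,3.376
AWT,control,66,17.105,2.411
VWT,IHD,91,15.524,3.686
VWT,MA,29,14.774,3.489
VWT,control,66,14.671,3.335
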