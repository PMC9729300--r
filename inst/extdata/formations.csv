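formation,slot,role,xmin,ymin,xmax,ymax
3-5-2,1,G,-55,-20,-38.5,20
3-5-2,2,lCB,-52,2,-15,28
3-5-2,3,CB,-52,-13,-15,13
3-5-2,4,rCB,-52,-28,-15,-2
3-5-2,5,lB,-45,14,25,30
3-5-2,6,lMF,-35,0,20,22
3-5-2,7,CMF,-35,-11,20,11
3-5-2,8,rMF,-35,-22,20,0
3-5-2,9,rB,-45,-30,25,-14
3-5-2,10,lF,-15,-2,52,24
3-5-2,11,rF,-15,-24,52,2
4-4-2,1,G,-55,-20,-38.5,20
4-4-2,2,lB,-52,16,0,30
4-4-2,3,lCB,-52,1,-10,18
4-4-2,4,rCB,-52,-18,-10,-1
4-4-2,5,rB,-52,-30,0,-16
4-4-2,6,lMF,-30,12,25,30
4-4-2,7,lCMF,-30,-2,20,16
4-4-2,8,rCMF,-30,-16,20,2
4-4-2,9,rMF,-30,-30,25,-12
4-4-2,10,lF,-10,0,52,24
4-4-2,11,rF,-10,-24,52,0
4-3-3,1,G,-55,-20,-38.5,20
4-3-3,2,rB,-52,-30,0,-16
4-3-3,3,lB,-52,16,0,30
4-3-3,4,rCB,-52,-18,-10,-1
4-3-3,5,lCB,-52,1,-10,18
4-3-3,6,CMF,-32,-11,18,11
4-3-3,7,rMF,-32,-26,18,-4
4-3-3,8,lMF,-32,4,18,26
4-3-3,9,CF,-12,-11,52,11
4-3-3,10,rF,-12,-30,52,-8
4-3-3,11,lF,-12,-8,52,30
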