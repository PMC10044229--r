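type,bark,croak,cry,gloo,gloogloo,groan,scream,whine,whoo,wom,wop
bark,271,2,2,11,1,0,0,0,0,4,3
croak,15,14,0,2,0,1,0,0,0,0,0
cry,9,0,12,0,0,1,0,0,0,0,2
gloo,17,2,0,44,2,2,0,0,0,9,0
gloogloo,7,0,0,1,19,11,0,0,0,1,0
groan,9,0,0,0,8,61,0,0,0,0,0
scream,0,0,0,0,0,0,15,0,4,0,0
whine,0,0,0,0,0,0,0,46,1,0,0
whoo,0,0,0,0,0,0,1,2,62,0,0
wom,6,0,0,10,0,2,0,0,0,24,0
wop,4,0,1,0,0,0,0,0,0,0,18
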