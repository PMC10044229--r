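type,growl,hiccup,squeak
growl,441,1,0
hiccup,0,199,11
squeak,1,19,23
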