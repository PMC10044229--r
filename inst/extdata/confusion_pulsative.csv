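type,clap,knock,rumble
clap,13,0,0
knock,0,222,2
rumble,0,2,21
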