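name,class,category,inhibitory
SNL,SN,sensory,FALSE
SNR,SN,sensory,FALSE
INL,IN,inter,FALSE
INR,IN,inter,FALSE
CM1,CM,inter,TRUE
CM2,CM,inter,TRUE
CM3,CM,inter,FALSE
MA1,MA,motor,FALSE
MA2,MA,motor,FALSE
MB1,MB,motor,FALSE
MD1,MD,motor,TRUE
MD2,MD,motor,TRUE
BY1,BY,inter,FALSE
BY2,BY,inter,FALSE
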