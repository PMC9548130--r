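pre,post,type,weight
INL,SNL,gap,3
BY1,SNL,gap,3
INR,SNR,gap,3
BY2,SNR,gap,3
SNL,INL,gap,3
SNR,INR,gap,3
SNL,BY1,gap,3
SNR,BY2,gap,3
CM2,INL,chemical,8
CM2,INR,chemical,8
INL,CM1,chemical,4
INR,CM1,chemical,4
CM1,CM2,chemical,8
INL,CM3,chemical,4
INR,CM3,chemical,4
CM1,MA1,chemical,4
CM1,MA2,chemical,4
CM1,MB1,chemical,4
CM3,MD1,chemical,4
CM3,MD2,chemical,4
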