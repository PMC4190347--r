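>RXR_like
A [ 95  2  1  2  2  3 ]
C [  1  1  1  1 94  2 ]
G [  2 95 96  2  2  2 ]
T [  2  2  2 95  2 93 ]
>RREB_like
A [  2  2  2  2 94 94 95  2 ]
C [ 94 95 94 95  2  2  2 94 ]
G [  2  1  2  1  2  2  1  2 ]
T [  2  2  2  2  2  2  2  2 ]
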