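>SYN0001 SP1
A [  2  1  1  1  2  1  1  2  1 ]
C [  1  1  1  1 16  1  1  1 16 ]
G [ 16 17 17 17  1 17 17 16  2 ]
T [  1  1  1  1  1  1  1  1  1 ]
>SYN0002 MYC
A [  1 17  1  1  1  1 ]
C [ 17  1 17  1  1  2 ]
G [  1  1  1 17  1 16 ]
T [  1  1  1  1 17  1 ]
>SYN0003 NFKB
A [  1  1  1 16  2  1  1  1  2  1 ]
C [  1  1  1  2 16  1  1  2 16 16 ]
G [ 17 17 17  1  1  1  1  1  1  2 ]
T [  1  1  1  1  1 17 17 16  1  1 ]
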