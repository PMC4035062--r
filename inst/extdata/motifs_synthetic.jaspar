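>SYN0001.1 AP1_syn
A [  1  1 17  1  1  1 17 ]
C [  1  1  1 17  1 17  1 ]
G [  1 17  1  1  1  1  1 ]
T [ 17  1  1  1 17  1  1 ]
>SYN0002.1 FOXA_syn
A [  2  1  1  2  2 14  1 ]
C [  2  1  1  2  2  2 15 ]
G [ 14  1  1  2  2  2  2 ]
T [  2 17 17 14 14  2  2 ]
>SYN0003.1 TP63_syn
A [  2 14  1  2 12  2 ]
C [ 14  2  1  2  2  2 ]
G [  2  2  1 14  4  2 ]
T [  2  2 17  2  2 14 ]
>SYN0004.1 ETS_syn
A [  1  1 16 16  2  1 ]
C [  2  1  1  1  2  2 ]
G [ 16 17  2  2 14  2 ]
T [  1  1  1  1  2 15 ]
>SYN0005.1 NFY_syn
A [  1  1 16 16  1 ]
C [ 17 16  1  1  2 ]
G [  1  2  2  2  1 ]
T [  1  1  1  1 16 ]
>SYN0006.1 MYB_syn
A [  2 14 14  1  2  2 ]
C [ 14  2  2 16  1  2 ]
G [  2  2  2  2 15 14 ]
T [  2  2  2  1  2  2 ]
>SYN0007.1 NR_syn
A [ 15  1  1  2  1 14 ]
C [  2  1  1 14  2  2 ]
G [  2 17 16  2  2  2 ]
T [  1  1  2  2 15  2 ]
>SYN0008.1 TCF_syn
A [  1  2  1  1  2 14 ]
C [ 16  2  1  1  2  2 ]
G [  1  2  2  2 14  2 ]
T [  2 14 16 16  2  2 ]
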