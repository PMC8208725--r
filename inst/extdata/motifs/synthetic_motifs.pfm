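>LDTF_ETSlike LDTF_ETSlike
A [  550  150  850  122  122  850  850  122  150  150 ]
C [  150  150  122   14   14  122  122   14  150  150 ]
G [  150  550   14  850  850   14   14  850  150  550 ]
T [  150  150   14   14   14   14   14   14  550  150 ]
>LDTF_CEBPlike LDTF_CEBPlike
A [  550  150  122  122  122  122  122  850  550  150 ]
C [  150  150   14   14  850   14  850  122  150  150 ]
G [  150  150   14  850   14  850   14   14  150  150 ]
T [  150  550  850   14   14   14   14   14  150  550 ]
>SDTF_GASlike SDTF_GASlike
A [  122  122  122  150  550  550  150  122  850  850 ]
C [   14   14  850  550  150  150  150   14  122  122 ]
G [   14   14   14  150  150  150  550  850   14   14 ]
T [  850  850   14  150  150  150  150   14   14   14 ]
>SDTF_EGRlike SDTF_EGRlike
A [  150  122  122  122  122  122  122  150  150  150 ]
C [  150  850   14   14   14   14   14  550  150  150 ]
G [  550   14  850   14  850  850  850  150  550  550 ]
T [  150   14   14  850   14   14   14  150  150  150 ]
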