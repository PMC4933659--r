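>tr|T00001|TRB1_SYNTH synthetic secondary-tier protein 1
MAGWCYDNTHSECONDPEPKVQRMFWTYHCAND
>tr|T00002|TRB2_SYNTH synthetic secondary-tier protein 2
MQDNCWHYTTRSHAREDKGVAFMYWCHTDN
>tr|T00003|TRB3_SYNTH synthetic secondary-tier protein 3
MVGAYCWNDHTRSHAREDKQFMEWYTCHDNA
>tr|T00004|TRB4_SYNTH synthetic secondary-tier protein 4
MWCDYNHGTAQKRFVMETWHYCDGNAK
>tr|T00005|TRB5_SYNTH synthetic secondary-tier protein 5
MCYWDHNGQTAVKRMFESTWYHCDGNA
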