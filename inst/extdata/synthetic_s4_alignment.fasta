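>synthetic_s4_01
DKSTYIRHWRTLREDYDAKNF
>synthetic_s4_02
DKSTYERVWRQLRVDYDAFNK
>synthetic_s4_03
DKSTIFRVWRTLRANYDAIPH
>synthetic_s4_04
DKSKYQRVWRALRAPYDAINF
>synthetic_s4_05
DKLGYIRVWRTKRADYGAINF
>synthetic_s4_06
DKSTYIRVWRVQRADYDAYNF
>synthetic_s4_07
DKSTYIRVWRKLRNDYDATNF
>synthetic_s4_08
DHSTYIREWRGLRAYYDAINF
>synthetic_s4_09
DKSTYIRVWRTIRADYDQIKF
>synthetic_s4_10
DKSTYLRVWRILRKDYLAIHQ
>synthetic_s4_11
IKSSYIRVWRTLRAQYDAIQF
>synthetic_s4_12
YKSTYIRVWRTLRANLDAIDY
>synthetic_s4_13
DKSTYIRVWRLHRAFYDAINF
>synthetic_s4_14
DKSKYIRVWRHLRAQYKAINF
>synthetic_s4_15
DDVTYIRVWRTLRADYGAINF
>synthetic_s4_16
DKSAYIRVWRTLRADYDYGNG
>synthetic_s4_17
DKSTYPRVWRTLRASYDAKNF
>synthetic_s4_18
DFSNYIRVWRTLRADASHINF
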