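AAAAAAAA
AAAAAAAG
AAAAAATA
AAAAAATG
AAAAATAA
AAAAATAG
AAAAATTA
AAAAATTG
AAAATAAA
AAAATAAG
AAAATATA
AAAATATG
AAAATTAA
AAAATTAG
AAAATTTA
AAAATTTG
AAATAAAA
AAATAAAG
AAATAATA
AAATAATG
AAATATAA
AAATATAG
AAATATTA
AAATATTG
AAATTAAA
AAATTAAG
AAATTATA
AAATTATG
AAATTTAA
AAATTTAG
AAATTTTA
AAATTTTG
AACAAAAA
AACAAAAG
AACAAATA
AACAAATG
AACAATAA
AACAATAG
AACAATTA
AACAATTG
AACATAAA
AACATAAG
AACATATA
AACATATG
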