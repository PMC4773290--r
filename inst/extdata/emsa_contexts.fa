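>rs6690733
ATCAAAAGGGGGTAAACACTACTACGTATAC
>rs10889352
GCAAACAGAAAAAAATATAGTACTAGTAAAA
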