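>sp|P00001|PRA1_SYNTH synthetic curated-tier protein 1
MKTAYIAKQRGDFEWNCMSPEPTIDEAVKHGTWNCFRMQ
>sp|P00002|PRA2_SYNTH synthetic curated-tier protein 2
MGHQWNTCASHAREDSEGKVFMDYTRNACHEWK
>sp|P00003|PRA3_SYNTH synthetic curated-tier protein 3
MNDCFWYHTSHAREDSEGKQVMGATRYHCWEFND
>sp|P00004|PRA4_SYNTH synthetic curated-tier protein 4
MTVKYHWDNFQAGRSEQCMKDTWYHFANGC
>sp|P00005|PRA5_SYNTH synthetic curated-tier protein 5
MHCWDNYGTAKQRVFEMSTHWCYDGNAKF
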