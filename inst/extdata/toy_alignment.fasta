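>a1
ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
>a2
GCGTACGTACGTACGTACGTACGTACGTACGTACGTACGN
>b1
ACGTGCGTATGTACCTACGAACGTACGTACGTACGTACGT
>c1
ACGTACGTACGTACGTACGTACGTGTACAGCGCCGTACGT
>c2
ACGTACGTACGTACGTACGTACGTGTACAGCGCCGTGCGT
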