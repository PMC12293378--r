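# 26-gene tumor immune expression signature (one symbol per line)
CCL5
CD2
CD244
CD247
CD3E
CD3G
CD6
CD8B
CD96
CST7
EOMES
GFI1
GPR18
GRAP2
IL7R
ITK
KCNA3
KLRD1
NLRC3
PRF1
PSTPIP1
SH2D1A
SIT1
THEMIS
TRAT1
XCL2
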