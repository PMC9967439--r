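config,wedge,symbol,P,minus_E_Ha,alpha
D4h,C of C=C,C,1.991,12.474,0.329
D4h,C of C-C,C,1.991,12.474,0.329
D4h,C of C-H,C,2.053,12.916,0.343
D4h,H of C-H,H,0.924,0.553,1
D2h,C of C=C,C,2.521,15.506,0.407
D2h,C of C-C,C,1.546,10.043,0.267
D2h,C of C-H,C,1.968,12.325,0.327
D2h,H of C-H,H,0.922,0.552,1
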