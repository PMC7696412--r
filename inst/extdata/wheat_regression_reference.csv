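genotype,response,slope,intercept,r2_percent,pearson_r
Yecora-Rojo,LA,0.008,178.85,88.9,0.94
Yecora-Rojo,LDW,0.066,149.1,98.4,0.99
Yecora-Rojo,BIO,0.5709,-11956,85.6,0.93
Seri-82,LA,0.0188,-81.859,98.0,0.99
Seri-82,LDW,0.1187,-782.3,97.9,0.99
Seri-82,BIO,0.3982,-8430.7,91.2,0.95
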