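genotype,trait,dap_start,dap_end,printed,unit
Yecora-Rojo,LDW,21,25,309,mg g-1 d-1
Yecora-Rojo,LDW,25,30,173.9,mg g-1 d-1
Yecora-Rojo,LDW,30,35,41.2,mg g-1 d-1
Yecora-Rojo,LDW,35,39,31.7,mg g-1 d-1
Yecora-Rojo,LDW,39,44,41.1,mg g-1 d-1
Yecora-Rojo,LDW,44,49,14.2,mg g-1 d-1
Yecora-Rojo,LDW,49,53,19.4,mg g-1 d-1
Yecora-Rojo,BIO,21,25,372.3,mg g-1 d-1
Yecora-Rojo,BIO,25,30,306.6,mg g-1 d-1
Yecora-Rojo,BIO,30,35,200.7,mg g-1 d-1
Yecora-Rojo,BIO,35,39,99,mg g-1 d-1
Yecora-Rojo,BIO,39,44,123.3,mg g-1 d-1
Yecora-Rojo,BIO,44,49,75.1,mg g-1 d-1
Yecora-Rojo,BIO,49,53,64.6,mg g-1 d-1
Yecora-Rojo,SPA,21,25,0.196,mm2 mm-2 d-1
Yecora-Rojo,SPA,25,30,0.141,mm2 mm-2 d-1
Yecora-Rojo,SPA,30,35,0.059,mm2 mm-2 d-1
Yecora-Rojo,SPA,35,39,0.059,mm2 mm-2 d-1
Yecora-Rojo,SPA,39,44,0.05,mm2 mm-2 d-1
Yecora-Rojo,SPA,44,49,0.008,mm2 mm-2 d-1
Yecora-Rojo,SPA,49,53,0.006,mm2 mm-2 d-1
Seri-82,LDW,21,25,345.5,mg g-1 d-1
Seri-82,LDW,25,30,335.9,mg g-1 d-1
Seri-82,LDW,30,35,106,mg g-1 d-1
Seri-82,LDW,35,39,79.6,mg g-1 d-1
Seri-82,LDW,39,44,76,mg g-1 d-1
Seri-82,LDW,44,49,29.9,mg g-1 d-1
Seri-82,LDW,49,53,4.8,mg g-1 d-1
Seri-82,BIO,21,25,349.3,mg g-1 d-1
Seri-82,BIO,25,30,352,mg g-1 d-1
Seri-82,BIO,30,35,170.2,mg g-1 d-1
Seri-82,BIO,35,39,90.9,mg g-1 d-1
Seri-82,BIO,39,44,115.7,mg g-1 d-1
Seri-82,BIO,44,49,142.8,mg g-1 d-1
Seri-82,BIO,49,53,65.3,mg g-1 d-1
Seri-82,SPA,21,25,0.251,mm2 mm-2 d-1
Seri-82,SPA,25,30,0.147,mm2 mm-2 d-1
Seri-82,SPA,30,35,0.072,mm2 mm-2 d-1
Seri-82,SPA,35,39,0.063,mm2 mm-2 d-1
Seri-82,SPA,39,44,0.041,mm2 mm-2 d-1
Seri-82,SPA,44,49,0.054,mm2 mm-2 d-1
Seri-82,SPA,49,53,-0.007,mm2 mm-2 d-1
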