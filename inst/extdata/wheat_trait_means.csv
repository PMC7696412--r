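genotype,trait,unit,dap,mean,se
Yecora-Rojo,LA,cm2,21,160,17
Yecora-Rojo,LA,cm2,25,367,55
Yecora-Rojo,LA,cm2,30,601,34
Yecora-Rojo,LA,cm2,35,649,28
Yecora-Rojo,LA,cm2,39,726,49
Yecora-Rojo,LA,cm2,44,756,31
Yecora-Rojo,LA,cm2,49,771,31
Yecora-Rojo,LA,cm2,53,810,30
Yecora-Rojo,LDW,mg,21,720,70
Yecora-Rojo,LDW,mg,25,1610,280
Yecora-Rojo,LDW,mg,30,3010,120
Yecora-Rojo,LDW,mg,35,3630,110
Yecora-Rojo,LDW,mg,39,4090,240
Yecora-Rojo,LDW,mg,44,4930,100
Yecora-Rojo,LDW,mg,49,5280,90
Yecora-Rojo,LDW,mg,53,5690,90
Yecora-Rojo,BIO,mg,21,920,90
Yecora-Rojo,BIO,mg,25,2290,460
Yecora-Rojo,BIO,mg,30,5800,460
Yecora-Rojo,BIO,mg,35,11620,390
Yecora-Rojo,BIO,mg,39,16220,980
Yecora-Rojo,BIO,mg,44,26220,740
Yecora-Rojo,BIO,mg,49,36070,1540
Yecora-Rojo,BIO,mg,53,45390,910
Yecora-Rojo,SPA,mm2,21,12542,960
Yecora-Rojo,SPA,mm2,25,22359,2463
Yecora-Rojo,SPA,mm2,30,38115,2198
Yecora-Rojo,SPA,mm2,35,49408,1175
Yecora-Rojo,SPA,mm2,39,61093,2732
Yecora-Rojo,SPA,mm2,44,76230,2238
Yecora-Rojo,SPA,mm2,49,79450,1476
Yecora-Rojo,SPA,mm2,53,81479,2137
Seri-82,LA,cm2,21,118,13
Seri-82,LA,cm2,25,290,33
Seri-82,LA,cm2,30,572,34
Seri-82,LA,cm2,35,884,45
Seri-82,LA,cm2,39,1173,85
Seri-82,LA,cm2,44,1594,158
Seri-82,LA,cm2,49,1887,77
Seri-82,LA,cm2,53,1800,105
Seri-82,LDW,mg,21,550,70
Seri-82,LDW,mg,25,1300,150
Seri-82,LDW,mg,30,3510,400
Seri-82,LDW,mg,35,5000,300
Seri-82,LDW,mg,39,7080,350
Seri-82,LDW,mg,44,10000,800
Seri-82,LDW,mg,49,11240,520
Seri-82,LDW,mg,53,11450,650
Seri-82,BIO,mg,21,730,100
Seri-82,BIO,mg,25,1800,200
Seri-82,BIO,mg,30,5000,400
Seri-82,BIO,mg,35,9000,500
Seri-82,BIO,mg,39,12000,190
Seri-82,BIO,mg,44,19000,1000
Seri-82,BIO,mg,49,32980,1030
Seri-82,BIO,mg,53,41600,2310
Seri-82,SPA,mm2,21,10882,1006
Seri-82,SPA,mm2,25,21795,1752
Seri-82,SPA,mm2,30,37825,1526
Seri-82,SPA,mm2,35,51398,2765
Seri-82,SPA,mm2,39,64438,4029
Seri-82,SPA,mm2,44,77526,4491
Seri-82,SPA,mm2,49,107159,1534
Seri-82,SPA,mm2,53,105419,2887
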