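sample_id,place,lon,lat,elevation_m,d13c
SNX,Shaanxi (Ningshan),108.1420,33.3484,1127,-23.4428
SCD,Sichuan (Chengdu),103.6889,30.6156,380,-24.1002
SWH,Shandong (Weihai),122.1005,36.5006,22,-24.1352
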