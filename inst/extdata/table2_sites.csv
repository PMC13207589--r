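site_id,place,lon,lat,elevation_m,d13c_mean,d13c_sd,n,bio1,bio2,bio3,bio4,bio5,bio6,bio7,bio8,bio9,bio10,bio11,bio12,bio13,bio14,bio15,bio16,bio17,bio18,bio19,bio20,bio21
KX,Gansu (Kangxian),105.54,33.30,1900.00,-23.56,0.02,5,11.14,8.68,29.39,761.01,25.56,-3.96,29.53,19.31,1.36,20.30,1.36,686.00,134.00,3.00,82.31,362.00,14.00,340.00,14.00,409.51,5127.62
LY,Hunan (Liuyang),113.61,28.15,1150.00,-24.53,0.10,5,17.27,7.77,24.90,853.72,32.90,1.69,31.21,21.51,8.41,27.47,6.50,1468.00,219.00,46.00,49.03,638.00,184.00,452.00,204.00,406.26,3678.12
TR,Guizhou (Tongren),109.26,27.82,2000.00,-25.28,0.11,5,16.14,8.19,27.56,793.99,30.94,1.22,29.72,20.23,6.09,25.62,6.09,1261.00,210.00,30.00,58.04,558.00,107.00,478.00,107.00,409.79,2830.01
HZ,Zhejiang (Hangzhou),119.44,30.35,1500.00,-23.95,0.05,5,11.74,7.27,24.45,820.71,26.24,-3.48,29.72,19.49,3.43,21.60,1.38,1550.00,241.00,40.00,49.38,608.00,156.00,607.00,173.00,407.09,4693.32
XY,Henan (Xingyang),114.10,31.81,143.00,-25.26,0.05,5,13.44,8.20,26.00,868.19,28.50,-3.04,31.54,23.87,2.40,23.87,2.40,1182.00,213.00,20.00,59.29,521.00,93.00,521.00,93.00,411.25,5355.72
JC,Shanxi (Jincheng),112.17,35.69,814.00,-22.79,0.21,5,10.38,11.10,30.18,967.53,27.72,-9.07,36.79,20.46,-2.11,21.86,-2.11,575.00,140.00,4.00,92.37,340.00,16.00,324.00,16.00,404.78,5665.75
ES,Hubei (Enshi),109.49,30.30,1200.00,-24.19,0.07,5,16.49,7.74,25.99,796.84,31.85,2.08,29.77,23.99,6.38,26.04,6.38,1467.00,244.00,26.00,63.11,654.00,91.00,637.00,91.00,407.28,3931.23
PZH,Sichuan (Panzhihua),101.74,26.50,1800.00,-22.81,0.07,5,19.96,11.78,46.64,480.47,30.74,5.49,25.25,24.92,13.58,24.93,13.58,766.00,168.00,6.00,94.15,454.00,21.00,365.00,21.00,413.52,8864.60
QN,Jiangxi (Quannan),114.39,24.65,329.00,-24.47,0.06,5,19.19,8.64,32.14,661.90,31.65,4.76,26.89,22.86,12.09,26.68,10.54,1726.00,306.00,37.00,63.03,810.00,139.00,622.00,193.00,412.45,6131.11
NJ,Jiangsu (Nanjing),118.89,31.33,100.00,-24.31,0.16,5,16.08,7.45,23.35,904.14,31.63,-0.28,31.92,24.56,6.83,26.91,4.64,1157.00,183.00,30.00,49.88,473.00,125.00,471.00,128.00,412.80,5538.57
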