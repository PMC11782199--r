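family,index,n,value
OT,IRDIF,1,54
OT,IRDIF,2,216
OT,IRDIF,3,486
OT,IRDIF,4,864
OT,IRDIF,5,1350
OT,AL,1,144
OT,AL,2,576
OT,AL,3,1296
OT,AL,4,2304
OT,AL,5,3600
OT,IRL,1,24.953299
OT,IRL,2,99.813196
OT,IRL,3,224.579691
OT,IRL,4,399.252784
OT,IRL,5,623.832475
OT,IRLU,1,36
OT,IRLU,2,144
OT,IRLU,3,324
OT,IRLU,4,576
OT,IRLU,5,900
OT,IRLF,1,25.455844
OT,IRLF,2,101.823376
OT,IRLF,3,229.102596
OT,IRLF,4,407.293504
OT,IRLF,5,636.3961
OT,IRF,1,576
OT,IRF,2,2304
OT,IRF,3,5184
OT,IRF,4,9216
OT,IRF,5,14400
OT,IRLA,1,24
OT,IRLA,2,96
OT,IRLA,3,216
OT,IRLA,4,384
OT,IRLA,5,600
OT,IRD1,1,57.939768
OT,IRD1,2,231.759072
OT,IRD1,3,521.457912
OT,IRD1,4,927.036288
OT,IRD1,5,1448.494200
OT,IRA,1,0.772078
OT,IRA,2,3.088312
OT,IRA,3,6.948702
OT,IRA,4,12.353248
OT,IRA,5,19.30195
OT,IRGA,1,4.240189
OT,IRGA,2,16.960756
OT,IRGA,3,38.161701
OT,IRGA,4,67.843024
OT,IRGA,5,106.004725
OT,IRB,1,24.70649
OT,IRB,2,98.82596
OT,IRB,3,222.35841
OT,IRB,4,395.30384
OT,IRB,5,617.66225
OT,IRRt,1,72
OT,IRRt,2,288
OT,IRRt,3,648
OT,IRRt,4,1152
OT,IRRt,5,1800
IS,IRDIF,1,72
IS,IRDIF,2,306
IS,IRDIF,3,702
IS,IRDIF,4,1260
IS,IRDIF,5,1980
IS,AL,1,240
IS,AL,2,1020
IS,AL,3,2340
IS,AL,4,4200
IS,AL,5,6600
IS,IRL,1,33.271056
IS,IRL,2,141.40198
IS,IRL,3,324.392796
IS,IRL,4,582.24348
IS,IRL,5,914.954040
IS,IRLU,1,48
IS,IRLU,2,204
IS,IRLU,3,468
IS,IRLU,4,840
IS,IRLU,5,1320
IS,IRLF,1,33.941136
IS,IRLF,2,144.249828
IS,IRLF,3,330.926076
IS,IRLF,4,593.969880
IS,IRLF,5,933.381240
IS,IRF,1,1200
IS,IRF,2,5100
IS,IRF,3,11700
IS,IRF,4,21000
IS,IRF,5,33000
IS,IRLA,1,32.000016
IS,IRLA,2,136.000068
IS,IRLA,3,312.000156
IS,IRLA,4,560.000280
IS,IRLA,5,880.000440
IS,IRD1,1,86.004432
IS,IRD1,2,365.518836
IS,IRD1,3,838.543212
IS,IRD1,4,1505.07756
IS,IRD1,5,2365.1218
IS,IRA,1,0.823536
IS,IRA,2,3.500028
IS,IRA,3,8.029476
IS,IRA,4,14.411880
IS,IRA,5,22.647240
IS,IRGA,1,2.826768
IS,IRGA,2,12.013764
IS,IRGA,3,27.560988
IS,IRGA,4,49.468440
IS,IRGA,5,77.736120
IS,IRB,1,41.177472
IS,IRB,2,175.004256
IS,IRB,3,401.480352
IS,IRB,4,720.736120
IS,IRB,5,1132.380480
IS,IRRt,1,120
IS,IRRt,2,510
IS,IRRt,3,1170
IS,IRRt,4,2100
IS,IRRt,5,3300
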