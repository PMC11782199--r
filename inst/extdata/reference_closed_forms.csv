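family,index,a2,a1
OT,IRDIF,54,0
OT,AL,144,0
OT,IRL,24.953299,0
OT,IRLU,36,0
OT,IRLF,25.455844,0
OT,IRF,576,0
OT,IRLA,24,0
OT,IRD1,57.9397648,0
OT,IRA,0.772078,0
OT,IRGA,4.240189,0
OT,IRB,24.70649,0
OT,IRRt,72,0
IS,IRDIF,81,-9
IS,AL,270,-30
IS,IRL,37.429938,-4.158883
IS,IRLU,54,-6
IS,IRLF,38.183778,-4.242641
IS,IRF,1350,-150
IS,IRLA,36,-4
IS,IRD1,96.7550,-10.75056
IS,IRA,0.926494,-0.102944
IS,IRGA,114.5513,-12.72792
IS,IRB,46.32468,-5.14719
IS,IRRt,135,-15
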