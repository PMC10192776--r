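name,temperature_C,pressure_bar,gibbs_kJ
oxalate,2.0,1.01,-672.57271
oxalate,2.0,250.0,-671.92299
oxalate,25.0,1.0,-673.9
oxalate,50.0,250.0,-674.19275
oxalate,100.0,1.0142,-675.2424
oxalate,100.0,250.0,-674.77662
oxalate,100.0,500.0,-674.27967
formate,2.0,1.01,-348.69589
formate,2.0,250.0,-348.03287
formate,25.0,1.0,-350.879
formate,50.0,250.0,-352.43002
formate,100.0,1.0142,-357.05154
formate,100.0,250.0,-356.46732
formate,100.0,500.0,-355.86817
bicarbonate,2.0,1.01,-584.63809
bicarbonate,2.0,250.0,-584.07694
bicarbonate,25.0,1.0,-586.94
bicarbonate,50.0,250.0,-588.73539
bicarbonate,100.0,1.0142,-594.1083
bicarbonate,100.0,250.0,-593.48753
bicarbonate,100.0,500.0,-592.84944
sulfate,2.0,1.01,-743.75494
sulfate,2.0,250.0,-743.49166
sulfate,25.0,1.0,-744.459
sulfate,50.0,250.0,-744.30642
sulfate,100.0,1.0142,-743.94886
sulfate,100.0,250.0,-743.6349
sulfate,100.0,500.0,-743.27707
methane,2.0,1.01,-32.68493
methane,2.0,250.0,-31.77046
methane,25.0,1.0,-34.451
methane,50.0,250.0,-35.84749
methane,100.0,1.0142,-43.04609
methane,100.0,250.0,-41.94224
methane,100.0,500.0,-40.86565
bisulfide,2.0,1.01,13.62874
bisulfide,2.0,250.0,14.09834
bisulfide,25.0,1.0,11.966
bisulfide,50.0,250.0,10.87135
bisulfide,100.0,1.0142,7.54482
bisulfide,100.0,250.0,8.03916
bisulfide,100.0,500.0,8.53992
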