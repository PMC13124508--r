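episode_id,variable_id,time_hours,value
ep0001,1,9.092,0.0993
ep0001,1,12.731,-0.7099
ep0001,1,14.124,-0.8107
ep0001,2,6.527,1.63
ep0001,2,8.325,1.2787
ep0001,2,23.139,-0.3704
ep0001,3,2.176,-0.5465
ep0001,3,7.236,-0.4994
ep0001,3,8.521,-1.1876
ep0001,3,19.185,-0.4835
ep0001,3,21.415,0.098
ep0001,4,4.559,-1.4106
ep0001,4,11.169,-1.6194
ep0002,1,11.609,-1.5663
ep0002,1,13.284,-2.0405
ep0002,1,14.121,-1.7175
ep0002,1,14.131,-1.7083
ep0002,1,14.14,-1.7186
ep0002,1,16.426,-1.4376
ep0002,1,21.537,0.1819
ep0002,2,6.064,0.2487
ep0002,2,7.653,0.6385
ep0002,2,8.8,0.5062
ep0002,2,11.326,-1.2138
ep0002,2,13.772,-2.5151
ep0002,2,16.356,-1.8899
ep0002,2,17.651,-0.5429
ep0002,3,2.45,1.1923
ep0002,3,7.928,-1.8804
ep0002,3,17.971,-0.8159
ep0002,3,20.629,0.6811
ep0002,4,2.313,-1.4381
ep0002,4,10.846,-0.795
ep0002,4,23.116,-0.9572
ep0003,1,21.681,0.5141
ep0003,1,21.812,0.6151
ep0003,1,22.37,0.801
ep0003,2,0.44,-0.4329
ep0003,2,6.685,0.6237
ep0003,2,9.051,0.8672
ep0003,2,9.261,0.6405
ep0003,2,14.804,-1.8018
ep0003,2,19.591,0.8396
ep0003,2,20.068,1.1304
ep0003,2,20.158,1.0294
ep0003,3,2.554,0.3821
ep0003,3,2.941,0.7307
ep0003,3,8.041,-1.9513
ep0003,3,14.548,-1.8255
ep0003,3,18.9,-0.2582
ep0003,3,22.472,-0.5656
ep0003,3,23.208,-1.0442
ep0003,4,0.327,-0.8475
ep0003,4,3.634,-1.854
ep0003,4,4.865,-2.6905
ep0003,4,5.924,-1.5331
ep0003,4,6.406,-0.9661
ep0003,4,13.038,-0.5076
ep0003,4,14.409,-0.7876
ep0003,4,14.763,-1.2649
ep0003,4,16.348,-2.4581
ep0003,4,17.571,-2.323
ep0003,4,23.095,-1.4271
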