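episode_id,variable_id,query_time_hours,target_value
ep0001,1,25.163,0.3215
ep0001,1,32.786,-0.2779
ep0001,1,40.187,-1.3432
ep0001,1,43.655,-0.8813
ep0001,2,30.818,0.894
ep0001,2,30.901,0.893
ep0001,2,31.336,0.8578
ep0001,2,42.308,-0.2417
ep0001,3,26.428,-0.3096
ep0001,3,32.92,-1.5622
ep0001,3,37.538,-0.6356
ep0001,3,44.303,-0.066
ep0001,4,25.734,-0.8523
ep0001,4,37.432,-1.3016
ep0001,4,37.663,-1.2497
ep0001,4,41.552,-1.8018
ep0002,1,24.637,0.6423
ep0002,1,27.293,0.4003
ep0002,1,28.929,0.005
ep0002,1,38.11,-1.7828
ep0002,2,28.063,-0.8628
ep0002,2,34.613,-0.6663
ep0002,2,37.803,-2.8207
ep0002,2,42.454,-0.4336
ep0002,3,35.608,-0.198
ep0002,3,36.945,-0.7477
ep0002,3,39.737,-3.0132
ep0002,3,46.451,-0.7132
ep0002,4,29.9,-0.9516
ep0002,4,32.698,0.4538
ep0002,4,45.144,-0.1432
ep0002,4,47.359,-0.7775
ep0003,1,31.532,-0.0965
ep0003,1,40.363,-0.0433
ep0003,1,41.399,0.1098
ep0003,1,43.07,0.3362
ep0003,2,31.373,1.1968
ep0003,2,34.122,0.6594
ep0003,2,42.155,0.3521
ep0003,2,45.903,1.498
ep0003,3,30.92,-1.1361
ep0003,3,34.902,-0.4404
ep0003,3,35.005,-0.3392
ep0003,3,47.006,-1.3879
ep0003,4,27.6,-2.0433
ep0003,4,28.892,-2.6064
ep0003,4,34.676,-1.2102
ep0003,4,44.298,0.3563
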