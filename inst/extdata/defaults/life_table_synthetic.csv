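family,e0_level,age_group_start,p5x
UN General,50,15,0.955
UN General,50,20,0.949
UN General,50,25,0.943
UN General,50,30,0.937
UN General,50,35,0.931
UN General,50,40,0.925
UN General,50,45,0.919
UN General,50,50,0.913
UN General,62.5,15,0.9635
UN General,62.5,20,0.9585
UN General,62.5,25,0.9535
UN General,62.5,30,0.9485
UN General,62.5,35,0.9435
UN General,62.5,40,0.9385
UN General,62.5,45,0.9335
UN General,62.5,50,0.9285
UN General,75,15,0.972
UN General,75,20,0.968
UN General,75,25,0.964
UN General,75,30,0.96
UN General,75,35,0.956
UN General,75,40,0.952
UN General,75,45,0.948
UN General,75,50,0.944
CD West,50,15,0.953
CD West,50,20,0.947
CD West,50,25,0.941
CD West,50,30,0.935
CD West,50,35,0.929
CD West,50,40,0.923
CD West,50,45,0.917
CD West,50,50,0.911
CD West,62.5,15,0.9615
CD West,62.5,20,0.9565
CD West,62.5,25,0.9515
CD West,62.5,30,0.9465
CD West,62.5,35,0.9415
CD West,62.5,40,0.9365
CD West,62.5,45,0.9315
CD West,62.5,50,0.9265
CD West,75,15,0.97
CD West,75,20,0.966
CD West,75,25,0.962
CD West,75,30,0.958
CD West,75,35,0.954
CD West,75,40,0.95
CD West,75,45,0.946
CD West,75,50,0.942
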