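record_id,species,mountain,location,elevation,trap_class,recapture,capture_day
r1,Maxomys whiteheadi,Toy,500,480,ground,FALSE,1
r2,Maxomys whiteheadi,Toy,500,520,ground,FALSE,2
r3,Tupaia montana,Toy,500,510,ground,FALSE,2
r4,Tupaia montana,Toy,500,505,ground,TRUE,4
r5,Sundamys muelleri,Toy,500,495,ground,FALSE,3
r6,Lenothrix canus,Toy,500,500,arboreal,FALSE,3
r7,Suncus sp.,Toy,500,500,pitfall,FALSE,5
r8,Tupaia montana,Toy,1500,1490,ground,FALSE,1
r9,Rattus baluensis,Toy,1500,1520,ground,FALSE,2
r10,Rattus baluensis,Toy,2400,2400,ground,FALSE,1
r11,Rattus baluensis,Toy,2400,2380,ground,FALSE,2
r12,Sundasciurus everetti,Toy,2400,2410,ground,FALSE,4
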