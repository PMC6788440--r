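mountain,location,trap_class,trap_nights
Toy,500,ground,300
Toy,500,arboreal,40
Toy,500,pitfall,20
Toy,1500,ground,320
Toy,2400,ground,280
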