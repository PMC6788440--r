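species,endemic,notes
Maxomys whiteheadi,non_endemic,
Tupaia montana,endemic,
Sundamys muelleri,non_endemic,
Lenothrix canus,non_endemic,
Suncus sp.,unknown,genus-level identification only
Rattus baluensis,endemic,
Sundasciurus everetti,endemic,
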