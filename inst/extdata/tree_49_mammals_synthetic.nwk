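((cape_golden_mole:0.04166666667,(elephant:0.02083333333,manatee:0.02083333333):0.02083333333):0.9583333333,((star_nosed_mole:0.4375,(((big_brown_bat:0.04166666667,(little_brown_bat:0.02083333333,davids_myotis_bat:0.02083333333):0.02083333333):0.04166666667,(large_flying_fox:0.02083333333,black_flying_fox:0.02083333333):0.0625):0.3333333333,((horse:0.02083333333,rhinoceros:0.02083333333):0.2916666667,((cat:0.1041666667,(dog:0.08333333333,((panda:0.02083333333,polar_bear:0.02083333333):0.04166666667,(ferret:0.02083333333,seal:0.02083333333):0.04166666667):0.02083333333):0.02083333333):0.1666666667,((cow:0.04166666667,(sheep:0.02083333333,goat:0.02083333333):0.02083333333):0.1041666667,(pig:0.08333333333,(alpaca:0.0625,((dolphin:0.02083333333,killer_whale:0.02083333333):0.02083333333,sperm_whale:0.04166666667):0.02083333333):0.02083333333):0.0625):0.125):0.04166666667):0.1041666667):0.02083333333):0.5,((tree_shrew:0.25,(bushbaby:0.2291666667,((marmoset:0.02083333333,squirrel_monkey:0.02083333333):0.1875,((baboon:0.0625,(rhesus_macaque:0.04166666667,(crab_eating_macaque:0.02083333333,green_monkey:0.02083333333):0.02083333333):0.02083333333):0.1041666667,(gibbon:0.08333333333,(orangutan:0.0625,(gorilla:0.04166666667,(human:0.02083333333,chimp:0.02083333333):0.02083333333):0.02083333333):0.02083333333):0.08333333333):0.04166666667):0.02083333333):0.02083333333):0.2291666667,(((squirrel:0.0625,(naked_mole_rat:0.04166666667,(guinea_pig:0.02083333333,degu:0.02083333333):0.02083333333):0.02083333333):0.1041666667,(blind_mole_rat:0.08333333333,((rat:0.02083333333,mouse:0.02083333333):0.04166666667,(prairie_vole:0.02083333333,deer_mouse:0.02083333333):0.04166666667):0.02083333333):0.08333333333):0.04166666667,(rabbit:0.02083333333,pika:0.02083333333):0.1875):0.2708333333):0.4583333333):0.0625);
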