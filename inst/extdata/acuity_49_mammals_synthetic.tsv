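species_id	va	source
cape_golden_mole	0	assumed_zero
star_nosed_mole	0	assumed_zero
blind_mole_rat	0	assumed_zero
naked_mole_rat	0.3	behavioral
big_brown_bat	0.6	behavioral
little_brown_bat	0.4	behavioral
davids_myotis_bat	0.5	proxy_relative
mouse	0.5	behavioral
prairie_vole	0.6	proxy_relative
deer_mouse	0.9	behavioral
rat	1.0	behavioral
manatee	1.2	behavioral
large_flying_fox	1.3	anatomical
black_flying_fox	1.4	anatomical
degu	1.8	behavioral
pika	2	proxy_relative
tree_shrew	2.5	behavioral
guinea_pig	2.7	behavioral
rabbit	3	behavioral
seal	3.5	anatomical
sperm_whale	4	anatomical
ferret	4	behavioral
squirrel	4	behavioral
dolphin	4.5	anatomical
bushbaby	5	behavioral
killer_whale	6	anatomical
rhinoceros	6	anatomical
panda	8	anatomical
cat	9	behavioral
pig	9	anatomical
polar_bear	10	anatomical
alpaca	10	anatomical
sheep	11	behavioral
goat	11	behavioral
cow	12	anatomical
dog	12	behavioral
elephant	13	behavioral
marmoset	25	behavioral
squirrel_monkey	25	behavioral
horse	25	behavioral
gibbon	30	anatomical
gorilla	35	anatomical
orangutan	35	anatomical
green_monkey	35	anatomical
baboon	40	behavioral
crab_eating_macaque	40	anatomical
rhesus_macaque	45	behavioral
chimp	45	anatomical
human	60	behavioral
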