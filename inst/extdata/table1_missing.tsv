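abbrev	species	tree_name	missing
acan	Acanthisitta chloris	passerine 1	885
anas	Anas platyrhynchos	outgroup 1	1201
apal	Apaloderma vittatum	trogon	700
apte	Aptenodytes forsteri	penguin 1	80
bale	Balearica regulorum	stork	242
buce	Buceros rhinoceros	hornbill	715
caly	Calypte anna	hummingbird	1072
capr	Antrostomus carolinensis	nightjar	431
cari	Cariama cristata	seriema	229
cath	Cathartes aura	NW vulture	206
chae	Chaetura pelagica	swift	886
char	Charadrius vociferus	killdeer	205
chla	Chlamydotis macqueenii	bustard	409
coli	Colius striatus	mousebird	886
colu	Columba livia	pigeon	557
corv	Corvus brachyrhynchos	passerine 2	907
cucu	Cuculus canorus	cuckoo	731
egre	Egretta garzetta	egret	213
eury	Eurypyga helias	sunbittern	585
falc	Falco peregrinus	falcon	290
fulm	Fulmarus glacialis	fulmar	184
gall	Gallus gallus	outgroup 2	1547
gavi	Gavia stellata	loon	184
geos	Geospiza fortis	passerine 3	1101
hala	Haliaeetus albicilla	eagle 1	162
hall	Haliaeetus leucocephalus	eagle 2	135
lept	Leptosomus discolor	cuckoo-roller	270
mana	Manacus vitellinus	passerine 4	833
mele	Meleagris gallopavo	outgroup 3	1644
melo	Melopsittacus undulatus	parrot 1	780
mero	Merops nubicus	bee-eater	746
mesi	Mesitornis unicolor	mesite	596
nest	Nestor notabilis	parrot 2	679
nipp	Nipponia nippon	ibis	128
opis	Opisthocomus hoazin	hoatzin	311
pele	Pelecanus crispus	pelican	164
phae	Phaethon lepturus	tropicbird	278
phal	Phalacrocorax carbo	cormorant	342
phoe	Phoenicopterus ruber	flamingo	193
pico	Picoides pubescens	woodpecker	1286
podi	Podiceps cristatus	grebe	377
pter	Pterocles gutturalis	sandgrouse	462
pygo	Pygoscelis adeliae	penguin 2	88
stru	Struthio camelus	outgroup 4	1317
taen	Taeniopygia guttata	passerine 5	1180
taur	Tauraco erythrolophus	turaco	342
tina	Tinamus guttatus	outgroup 5	1730
tyto	Tyto alba	owl	325
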