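code,label,class,tier,description
BIO,bioculturalism,value,secondary,People recognized as an integral and intrinsic part of the environment
CAB,commercial and business,value,secondary,Market-based and commercial activities associated with the environment
CEC,customary economy,value,secondary,Customary exchange and community trade of local resources
COM,commitment and caring for the environment,value,secondary,Commitment to and caring for the environment
CON,western conservation,value,secondary,Preservation-based conservation approaches treating humans as separate from nature
COT,recreation activities,value,secondary,Recreational engagement with the coastal environment
CUL,cultural expression,value,secondary,Expression of culture through practice and art
GOV,governance,value,secondary,Right and capacity to make decisions about place
HAR,harvesting,value,secondary,Customary harvest of foods and materials
ILK,indigenous and local knowledge,value,secondary,Knowledge systems tied to the local environment
HIS,ancestral activities,value,secondary,Historical and ancestral activities on the land and sea
MEN,mental health,value,secondary,Mental health and well-being supported by the environment
NOR,normalization of human-environment relationship,value,secondary,Normalization of the human-environment relationship
OPE,operationalization,value,secondary,Putting values and decisions into practice
PHY,physical health,value,secondary,Physical health supported by the environment
PRE,prestige,value,secondary,Prestige and authority to make decisions about place
PTA,people to ancestors,value,secondary,Identity and connection with ancestors
PTL,people to location,value,secondary,Identity and connection with place
PTP,people to people,value,secondary,Connections between people including future generations
SPI,spiritual health,value,secondary,Spiritual health and connection
STE,stewardship,value,secondary,Environmental stewardship and guardianship
TEA,teaching and learning processes,value,secondary,Inter-generational teaching and learning
SEA,sea,biophysical,,Open sea and coastal waters
PETRELS,grey-faced petrels,biophysical,,Grey-faced petrel colonies on the offshore islands
LANDBIRDS,land birds,biophysical,,Native land birds
FISH,marine fish,biophysical,,Marine fish species
SHELLFISH,shellfish,biophysical,,Intertidal and subtidal shellfish
GARDENS,gardens,biophysical,,Garden and horticultural sites
LAND,land,biophysical,,Island and coastal land
TUATARA,tuatara,biophysical,,Tuatara populations on the islands
SEABIRDS,other seabirds,biophysical,,Seabirds other than petrels (synthetic list entry)
ISLANDS,offshore islands,biophysical,,The offshore islands as a whole (synthetic list entry)
BEACHES,beaches,biophysical,,Beaches and foreshore (synthetic list entry)
ROCKS,rocky shore,biophysical,,Rocky shore platforms (synthetic list entry)
REEFS,reefs,biophysical,,Subtidal reef systems (synthetic list entry)
SAND,sand dunes,biophysical,,Dune systems (synthetic list entry)
CAVES,caves,biophysical,,Coastal caves (synthetic list entry)
SPRINGS,freshwater springs,biophysical,,Freshwater springs (synthetic list entry)
STREAMS,streams,biophysical,,Streams and waterways (synthetic list entry)
FOREST,coastal forest,biophysical,,Coastal forest remnants (synthetic list entry)
POHUTUKAWA,pohutukawa,biophysical,,Pohutukawa trees (synthetic list entry)
FLAX,harakeke flax,biophysical,,Harakeke flax stands (synthetic list entry)
KELP,kelp beds,biophysical,,Kelp beds (synthetic list entry)
SEAWEED,seaweed,biophysical,,Other seaweeds (synthetic list entry)
CRAYFISH,crayfish,biophysical,,Rock lobster (synthetic list entry)
KINA,kina,biophysical,,Sea urchin (synthetic list entry)
PAUA,paua,biophysical,,Abalone (synthetic list entry)
MUSSELS,mussels,biophysical,,Mussel beds (synthetic list entry)
PIPI,pipi,biophysical,,Pipi beds (synthetic list entry)
SNAPPER,snapper,biophysical,,Snapper (synthetic list entry)
KAHAWAI,kahawai,biophysical,,Kahawai (synthetic list entry)
EELS,eels,biophysical,,Freshwater eels (synthetic list entry)
SHARKS,sharks,biophysical,,Sharks (synthetic list entry)
DOLPHINS,dolphins,biophysical,,Dolphins (synthetic list entry)
WHALES,whales,biophysical,,Whales (synthetic list entry)
SEALS,fur seals,biophysical,,Fur seals (synthetic list entry)
OCTOPUS,octopus,biophysical,,Octopus (synthetic list entry)
LIZARDS,lizards and geckos,biophysical,,Lizards and geckos (synthetic list entry)
INSECTS,insects,biophysical,,Insects (synthetic list entry)
TIDES,tides,biophysical,,Tidal cycles (synthetic list entry)
CURRENTS,ocean currents,biophysical,,Ocean currents (synthetic list entry)
WINDS,winds,biophysical,,Prevailing winds (synthetic list entry)
MOON,moon and stars,biophysical,,Moon and stars used in navigation and harvest timing (synthetic list entry)
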