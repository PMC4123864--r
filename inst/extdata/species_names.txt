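Puma concolor
Lynx rufus
Canis latrans
Vulpes vulpes
Ursus americanus
Procyon lotor
Odocoileus virginianus
Cervus canadensis
Alces alces
Castor canadensis
Lontra canadensis
Mephitis mephitis
Didelphis virginiana
Sciurus carolinensis
Tamias striatus
Peromyscus maniculatus
Microtus pennsylvanicus
Sylvilagus floridanus
Lepus americanus
Erethizon dorsatum
Turdus migratorius
Cyanocitta cristata
Cardinalis cardinalis
Poecile atricapillus
Sitta carolinensis
Corvus brachyrhynchos
Buteo jamaicensis
Falco peregrinus
Haliaeetus leucocephalus
Ardea herodias
Anas platyrhynchos
Branta canadensis
Larus argentatus
Sterna hirundo
Melospiza melodia
Zonotrichia albicollis
Setophaga coronata
Vireo olivaceus
Hirundo rustica
Colaptes auratus
Thamnophis sirtalis
Chrysemys picta
Chelydra serpentina
Plethodon cinereus
Ambystoma maculatum
Lithobates catesbeianus
Anaxyrus americanus
Salmo trutta
Salvelinus fontinalis
Micropterus salmoides
Perca flavescens
Esox lucius
Danaus plexippus
Papilio glaucus
Bombus impatiens
Apis mellifera
Photinus pyralis
Acer saccharum
Quercus rubra
Pinus strobus
Tsuga canadensis
Betula papyrifera
Trillium grandiflorum
Asclepias syriaca
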