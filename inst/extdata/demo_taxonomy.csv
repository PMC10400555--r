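species,genus,family,tags,synonyms
Macruronus novaezelandiae,Macruronus,Merlucciidae,teleost,
Macruronus magellanicus,Macruronus,Merlucciidae,teleost,
Merluccius australis,Merluccius,Merlucciidae,teleost,
Penaeus monodon,Penaeus,Penaeidae,crustacean,
Penaeus plebejus,Penaeus,Penaeidae,crustacean,Melicertus plebejus
Penaeus latisulcatus,Penaeus,Penaeidae,crustacean,Melicertus latisulcatus
Penaeus merguiensis,Penaeus,Penaeidae,crustacean,Fenneropenaeus merguiensis
Penaeus esculentus,Penaeus,Penaeidae,crustacean,
Penaeus vannamei,Penaeus,Penaeidae,crustacean,Litopenaeus vannamei
Metapenaeus endeavouri,Metapenaeus,Penaeidae,crustacean,
Mustelus antarcticus,Mustelus,Triakidae,selachimorph,
Mustelus lenticulatus,Mustelus,Triakidae,selachimorph,
Galeorhinus galeus,Galeorhinus,Triakidae,selachimorph,
Carcharhinus obscurus,Carcharhinus,Carcharhinidae,selachimorph,
Carcharhinus plumbeus,Carcharhinus,Carcharhinidae,selachimorph,
Carcharhinus amboinensis,Carcharhinus,Carcharhinidae,selachimorph,
Prionace glauca,Prionace,Carcharhinidae,selachimorph,
Sphyrna zygaena,Sphyrna,Sphyrnidae,selachimorph,
Notorynchus cepedianus,Notorynchus,Hexanchidae,selachimorph,
Atlantoraja castelnaui,Atlantoraja,Arhynchobatidae,batoid,
Dasyatis brevicaudata,Dasyatis,Dasyatidae,batoid,
Callorhinchus milii,Callorhinchus,Callorhinchidae,holocephalan,Callorhinchus millii
Callorhinchus capensis,Callorhinchus,Callorhinchidae,holocephalan,
Callorhinchus callorynchus,Callorhinchus,Callorhinchidae,holocephalan,
Lutjanus erythropterus,Lutjanus,Lutjanidae,teleost,
Lutjanus malabaricus,Lutjanus,Lutjanidae,teleost,
Lutjanus sebae,Lutjanus,Lutjanidae,teleost,
Lutjanus argentimaculatus,Lutjanus,Lutjanidae,teleost,
Chrysophrys auratus,Chrysophrys,Sparidae,teleost,Pagrus auratus
Rhabdosargus sarba,Rhabdosargus,Sparidae,teleost,
Centroberyx affinis,Centroberyx,Berycidae,teleost,
Centroberyx gerrardi,Centroberyx,Berycidae,teleost,
Lethrinus nebulosus,Lethrinus,Lethrinidae,teleost,
Nemadactylus macropterus,Nemadactylus,Cheilodactylidae,teleost,
Oreochromis niloticus,Oreochromis,Cichlidae,teleost,
Oreochromis mossambicus,Oreochromis,Cichlidae,teleost,
Lates calcarifer,Lates,Latidae,teleost,
Protonibea diacanthus,Protonibea,Sciaenidae,teleost,
Parupeneus cyclostomus,Parupeneus,Mullidae,teleost,
Sepioteuthis australis,Sepioteuthis,Loliginidae,cephalopod;squid,
Uroteuthis chinensis,Uroteuthis,Loliginidae,cephalopod;squid,
Nototodarus gouldi,Nototodarus,Ommastrephidae,cephalopod;squid,
Dosidicus gigas,Dosidicus,Ommastrephidae,cephalopod;squid,
Sepia apama,Sepia,Sepiidae,cephalopod;cuttlefish,
Sepia officinalis,Sepia,Sepiidae,cephalopod;cuttlefish,
Octopus tetricus,Octopus,Octopodidae,cephalopod;octopod,
Thunnus maccoyii,Thunnus,Scombridae,teleost,
Thunnus thynnus,Thunnus,Scombridae,teleost,
Thunnus albacares,Thunnus,Scombridae,teleost,
Thunnus obesus,Thunnus,Scombridae,teleost,
Katsuwonus pelamis,Katsuwonus,Scombridae,teleost,
Gadus chalcogrammus,Gadus,Gadidae,teleost,Theragra chalcogramma
Sus scrofa,Sus,Suidae,mammal,
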