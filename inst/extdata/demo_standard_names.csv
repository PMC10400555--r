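name
blue grenadier
hoki
grenadier
tiger prawn
banana prawn
endeavour prawn
king prawn
prawn
flake
gummy shark
school shark
sandbar shark
smooth hammerhead
elephant fish
snapper
sea bream
saddletail snapper
squid
arrow squid
southern calamari
cuttlefish
giant cuttlefish
tuna
bluefin tuna
skipjack tuna
yellowfin tuna
southern bluefin tuna
atlantic bluefin tuna
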