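species,group,genus,subtribe,tribe,subfamily
Pasimachus strenuus,Pasimachus strenuus,Pasimachus,Pasimachina,Scaritini,Scaritinae
Pasimachus californicus,Pasimachus californicus,Pasimachus,Pasimachina,Scaritini,Scaritinae
Scarites subterraneus,Scarites subterraneus,Scarites,Scaritina,Scaritini,Scaritinae
Cyclotrachelus torvus,Cyclotrachelus torvus,Cyclotrachelus,Pterostichini,Pterostichini,Harpalinae
Cyclotrachelus furtivus,Cyclotrachelus furtivus,Cyclotrachelus,Pterostichini,Pterostichini,Harpalinae
Pterostichus trinarius,Pterostichus trinarius,Pterostichus,Pterostichini,Pterostichini,Harpalinae
Pterostichus commutabilis,Pterostichus commutabilis,Pterostichus,Pterostichini,Pterostichini,Harpalinae
Chlaenius aestivus,Chlaenius aestivus,Chlaenius,Chlaeniina,Chlaeniini,Harpalinae
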