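taxon,suborder,leverage,PHI_squared,product,gape,reach,designation,source
Achipteria coleoptrata,Oribatida,0.369,798.06,469.45,21.25,76.50,Primary decomposer,Perdomo et al. 2021
Amerus troisii,Oribatida,0.713,3721.00,2653.23,46.00,181.00,Microphytophage,Schuster 1956
Amerus troisii,Oribatida,0.299,676.00,338.00,22.00,87.00,Carnivore/Omnivore,Perdomo et al. 2021
Arcoplophora villosa,Oribatida,0.500,1225.00,612.50,25.00,82.50,Fragmentary feeder,Kaneko 1988
Austrachipteria sp. 1,Oribatida,0.404,1764.00,1177.53,30.80,104.00,Lichenivourous,Perdomo et al. 2021
Austrachipteria sp. 2,Oribatida,0.433,1936.00,1201.39,31.63,101.50,Secondary decomposer,Perdomo et al. 2021
Belba verticillipes,Oribatida,0.571,4761.00,2716.57,51.00,176.00,Microphytophage,Schuster 1956
Ceratoppia sexpilosa,Oribatida,0.544,4761.00,2588.79,48.00,169.00,Microphytophage,Schuster 1956
Ceratozetoidid,Oribatida,0.376,858.49,632.57,19.00,78.00,Secondary decomposer,Perdomo et al. 2021
Chamobates borealis,Oribatida,0.420,1667.36,1013.08,26.33,97.33,Secondary decomposer,Perdomo et al. 2021
Chamobates cuspidatus,Oribatida,0.396,3025.00,1932.64,36.00,139.00,Secondary decomposer,Perdomo et al. 2021
Chamobates voigtsi,Oribatida,0.453,1849.00,1280.08,26.00,95.00,Secondary decomposer,Perdomo et al. 2021
Crotonia sp.,Oribatida,0.405,1778.31,1042.27,35.83,104.25,Secondary decomposer,Perdomo et al. 2021
Cultroribatula sp.,Oribatida,0.443,1777.47,1235.19,29.50,95.20,Primary decomposer,Perdomo et al. 2021
Eohypochtonius magnus,Oribatida,0.231,625.00,144.23,32.50,95.00,Fragmentary feeder,Kaneko 1988
Epilohmannoides esculatus,Oribatida,0.667,3025.00,2016.67,52.50,125.00,Macrophytophage,Kaneko 1988
Euepicrius lootsi,Mesostigmata,0.305,1764.00,696.14,65.25,137.75,Carnivore/Omnivore,Perdomo et al. 2021
Eupelops sp.,Oribatida,0.375,2500.00,937.50,20.00,232.50,Microphytophage,Kaneko 1988
Gamasellus sp.,Mesostigmata,0.288,882.09,254.64,53.00,103.00,Carnivore/Omnivore,Perdomo et al. 2021
Gymnodamaeus bicostatus,Oribatida,0.693,3600.00,2493.66,41.00,136.00,Microphytophage,Schuster 1956
Hermaniella granulata,Oribatida,0.706,5184.00,3659.29,51.00,175.00,Macrophytophage,Schuster 1956
Heterobelba stellifera,Oribatida,0.444,756.25,336.11,22.50,87.50,Microphytophage,Kaneko 1988
Hypochthonius rufulus,Oribatida,0.268,361.00,152.00,19.00,71.00,Carnivore/Omnivore,Perdomo et al. 2021
Hypodamaeus riparius,Oribatida,0.388,1444.00,748.74,27.00,98.00,Secondary decomposer,Perdomo et al. 2021
Lanceoppia sp.,Oribatida,0.284,729.00,364.50,24.00,95.00,Carnivore/Omnivore,Perdomo et al. 2021
Liacarus acutidens,Oribatida,0.757,22500.00,17027.03,92.50,300.00,Microphytophage,Kaneko 1988
Malaconothrus talaitae,Oribatida,0.449,462.25,313.27,18.44,47.83,Primary decomposer,Perdomo et al. 2021
Nothrus palustris,Oribatida,0.479,1156.00,770.67,24.00,71.00,Primary decomposer,Perdomo et al. 2021
Nothrus silvestris,Oribatida,0.568,5625.00,3196.43,63.00,170.00,Non-specialised,Schuster 1956
Oppiella nova,Oribatida,0.429,400.00,171.43,17.50,55.00,Microphytophage,Kaneko 1988
Oribatula tibialis,Oribatida,0.429,729.00,592.31,16.00,63.00,Primary decomposer,Perdomo et al. 2021
Paradamaeus clavipes,Oribatida,0.407,3481.00,1779.18,45.00,145.00,Secondary decomposer,Perdomo et al. 2021
Phthiracarus sp.,Oribatida,0.477,3844.00,2506.96,46.00,130.00,Primary decomposer,Perdomo et al. 2021
Platynothrus peltifer,Oribatida,0.520,1521.00,1244.45,22.00,75.00,Primary decomposer,Perdomo et al. 2021
Protoribates lophotricus,Oribatida,0.667,6006.25,4004.17,52.50,157.50,Panphytophage,Kaneko 1988
Pseudoceratoppia sp.,Oribatida,0.374,1296.00,704.62,25.75,96.25,Secondary decomposer,Perdomo et al. 2021
Rhysotritia ardua,Oribatida,0.750,7225.00,5418.75,60.00,182.50,Macrophytophage,Kaneko 1988
Rhysotritia ardua,Oribatida,0.750,7225.00,5418.75,60.00,182.50,Panphytophage,Kaneko 1988
Steganacarus cf. clavigera,Oribatida,0.663,4900.00,3248.52,54.00,140.00,Macrophytophage,Schuster 1956
Tectocepheus velatus,Oribatida,0.432,256.00,186.18,11.00,37.00,Primary decomposer,Perdomo et al. 2021
Xenillus tegeocranus,Oribatida,0.741,6561.00,4860.00,54.00,202.00,Non-specialised,Schuster 1956
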