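biome,scheme,t_th_gdd,gdd_c,t_th_bbgc,a,b,c,d,k,t_th_ngd,ngd_c,t_th_ncd,t_th_ncdgdd,g,h,w
evergreen needleleaf forest,woody,6,50,0,4.755,0.117,,,,9,5,0,3,-300,400,-0.1
deciduous needleleaf forest,woody,2,52,0,4.755,0.117,,,,5,6,0,-1,-300,400,-0.1
deciduous broadleaf forest,woody,-5,591,-5,5.505,0.085,,,,6,21,0,-5,-100,700,-0.1
cool mixed forest,woody,5,52,0,4.63,0.101,,,,8,6,-5,3,-300,400,-0.1
warm mixed forest,woody,7,236,-5,6.005,0.057,,,,5,59,-5,5,-300,600,-0.1
cool closed shrub,woody,5,50,2,4.13,0.109,,,,8,5,-5,3,-300,400,-0.1
warm closed shrub,woody,7,308,-5,6.63,0.041,,,,5,77,-5,5,-300,700,-0.1
cool open shrub,woody,0,140,-3,5.505,0.057,,,,5,11,-5,1,-300,400,-0.1
warm open shrub,woody,7,350,-5,6.005,0.069,,,,10,41,-2,7,-300,600,-0.1
cool woody savanna,grass,3,58,0,,,15,119,0.05,7,6,-5,1,-300,400,-0.1
warm woody savanna,grass,7,296,-5,,,5,119,0.06,5,58,-5,5,-300,600,-0.1
savanna,grass,1,126,-2,,,11,209,0.16,5,12,-5,5,-300,400,-0.1
grassland,grass,-5,448,-5,,,15,369,0.05,6,12,-5,5,-300,400,-0.1
permanent wetland,woody,-5,378,-1,5.005,0.101,,,,-4,47,-5,1,-300,400,-0.1
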