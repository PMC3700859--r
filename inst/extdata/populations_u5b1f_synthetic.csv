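population_id,latitude,longitude,n,count
Guipuzcoa,43.20,-2.20,180,20
SW_Guipuzcoa,43.05,-2.40,60,7
Biscay,43.30,-2.90,150,12
West_Biscay,43.30,-3.20,55,3
Alava,42.85,-2.70,120,8
South_Alava,42.60,-2.60,40,2
Northern_Navarre,43.05,-1.70,110,19
CW_Navarre,42.70,-1.90,70,6
NE_Navarre,42.90,-1.30,50,5
NW_Navarre,43.10,-1.95,60,8
Lower_Navarre,43.20,-1.05,45,8
Labourdin,43.35,-1.45,85,14
Soule,43.15,-0.90,40,6
Bearn,43.20,-0.60,70,5
Bigorre,43.10,0.10,55,2
Chalosse,43.70,-0.80,50,3
La_Rioja,42.30,-2.45,80,2
Burgos,42.35,-3.70,90,1
Pas_Valley,43.15,-3.90,60,0
Cantabria,43.20,-4.00,100,0
Aragon,41.70,-0.90,70,1
Zaragoza,41.65,-0.88,65,1
NE_Spain,41.60,1.50,120,1
Madrid,40.40,-3.70,150,0
Perigord_Limousin,45.30,1.00,90,0
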