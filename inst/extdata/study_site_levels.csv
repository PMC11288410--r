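site_id,site_name,level_id,time_frame,n_total,n_shared
AR,Artusia,III,8600-8401,4,4
AR,Artusia,V,8200-7801,2,2
FAL,Abric de la Falguera,VIII,8400-8001,2,2
FAL,Abric de la Falguera,Xa,8400-8201,1,1
XI,Abric del Xicoto,II,7200-7001,4,2
AN2,Angel 2,2a2,8000-7801,12,12
AT,Atxoste,IV,8200-7601,62,60
AT,Atxoste,IIIb2,7600-7401,22,21
BAR,Barranquet,79,7600-7401,2,2
BE,Benamer,I,8400-8201,32,32
BE,Benamer,II,7600-7401,3,2
BO,Botiqueria dels Moros,2,8600-8201,43,42
BO,Botiqueria dels Moros,4,7800-7601,16,12
CAB,Cabezo de la Cruz,Cabana,8000-7801,8,8
COR,Casa Corona,LM,8000-7801,12,11
SP,Caserna de Sant Pau,IV-base,7400-7201,1,1
CAS,Castillejos,I,7400-6801,2,2
SA,Can Sadurni,18-IIIC,7400-7200,1,1
CRE,Cingle de Mas Cremat,VI,7800-7401,1,1
CRE,Cingle de Mas Cremat,V,7800-7601,8,8
CRE,Cingle de Mas Cremat,III,7000-6801,1,1
COS,Costamar,NII,7000-6801,12,10
COC,Cueva de la Cocina,A1,8600-8201,57,57
COC,Cueva de la Cocina,A2,8400-8001,85,85
COC,Cueva de la Cocina,B1,8000-7601,96,96
COC,Cueva de la Cocina,B2,8000-7601,173,173
COC,Cueva de la Cocina,B3,7800-7401,20,20
OR,Cova de l'Or,IV,7400-7001,11,10
OR,Cova de l'Or,V,7400-7201,27,26
OR,Cova de l'Or,VI,7400-7001,44,43
CE,Cova de les Cendres,XI,7600-7201,3,2
CE,Cova de les Cendres,X,7400-7001,1,0
CE,Cova de les Cendres,IX,7200-7001,2,2
CE,Cova de les Cendres,VIIa,7200-6801,1,1
TR,Cova dels Trocs,53,7000-6800,2,2
FEM,Coves del Fem,103,7600-7401,4,2
CH,Cueva de Chaves,Ib,7600-7201,38,23
CH,Cueva de Chaves,Ia,7200-7001,6,4
NE,Cueva de Nerja,NM10,7400-7201,5,4
NE,Cueva de Nerja,NV2,7200-7001,1,1
TO,Cueva del Toro,IV,7200-7001,4,4
VAC,El Abrigo de Valcervera,b,8000-7801,4,4
COL,El Collado,I-3,8600-8401,4,4
ESP,El Esplugon,3-inf,8000-7601,47,45
ESL,Espantalobos,c,8400-8201,7,7
FOR,Forcas II,II,8000-7801,14,14
FOR,Forcas II,IV,8000-7801,26,24
DR,La Draga,ABC,7200-6801,14,9
GUI,Les Guixeres de Vilobi,A,7600-7401,5,3
GUI,Les Guixeres de Vilobi,B,7000-6801,1,1
MIS,Mas d'Is,VIb,7600-7401,2,1
MN,Mas Nou,III-burial,7800-7600,2,2
PO,Pontet,e,8200-8001,14,14
VAM,Valmayor,XI-III,7000-6801,5,4
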