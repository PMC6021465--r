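code,name,inchikey,role,sites
1,"2,3-Diaminosuccinic acid",PGNYNCTUBKSHHL-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:1.90;c2:acidic:3.20;n1:basic:9.20;n2:basic:7.30
2,"2,4-Diaminoglutaric acid",LOPLXECQBMXEBQ-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:2.00;c2:acidic:3.40;n1:basic:9.50;n2:basic:8.00
3,"4-Amino-3-hydroxyglutamic acid",ROZOJQWPTMSEJM-NUWTVHIESA-N,carboxylic_acid,c1:acidic:2.10;c2:acidic:3.50;n1:basic:8.90
4,Aspartic acid,CKLJMWTZIZZHCS-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:1.99;c2:acidic:3.90;n1:basic:9.90
5,3-Hydroxyaspartic acid,YYLQUHNPNCGKJQ-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:1.90;c2:acidic:3.50;n1:basic:9.10
6,3-Aminoglutamic acid,BBJIPMIXTXKYLZ-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:2.10;c2:acidic:4.00;n1:basic:9.70
7,Glutamic acid,WHUUTDBJXJRKMK-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:2.16;c2:acidic:4.15;n1:basic:9.58
8,2-Amino-3-hydroxyglutamic acid,LKZIEAUIOCGXBY-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:2.10;c2:acidic:3.80;n1:basic:8.90
9,Aminomalonic acid,JINBYESILADKFW-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:1.70;c2:acidic:3.10;n1:basic:8.80
10,2-Amino-4-hydroxyglutamic acid,HBDWQSHEVMSFGY-STHAYSLISA-N,carboxylic_acid,c1:acidic:2.10;c2:acidic:3.90;n1:basic:9.00
11,2-Hydroxyglutamic acid,HWXBTNAVRSUOJR-VKHMYHEASA-N,carboxylic_acid,c1:acidic:2.70;c2:acidic:4.30
12,Hydroxymalonic acid,ROBFUDYVXSDBQM-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:2.40;c2:acidic:4.50
13,3-Hydroxyglutamic acid,ZQHYXNSQOIDNTL-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:3.00;c2:acidic:4.40
14,Glutaric acid,JFCQEDHGNNZCLN-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:4.31;c2:acidic:5.41
15,"2,4-Dihydroxyglutamic acid",FTWPXBYNGOWCHI-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:2.50;c2:acidic:3.90
16,Malic acid,BJEPYKJPYRNKOW-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:3.40;c2:acidic:5.11
17,Oxalic acid,MUBZPKHOEPUJKR-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:1.25;c2:acidic:4.14
18,Malonic acid,OFOBLEOULBTSOW-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:2.83;c2:acidic:5.69
19,Citric acid,KRKNYBCHXYNGOX-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:3.13;c2:acidic:4.76;c3:acidic:6.40
20,Succinic acid,KDYFGRWQOYBRFD-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:4.21;c2:acidic:5.64
21,Tartaric acid,FEWJPZIEWOKRBE-UHFFFAOYSA-N,carboxylic_acid,c1:acidic:2.98;c2:acidic:4.34
A,Proline,ONIBWKKTOPOVIA-BYPYZUCNSA-N,amino_acid,c1:acidic:1.99;n1:basic:10.60
B,Cycloleucine,NILQLFBWTXNUOE-UHFFFAOYSA-N,amino_acid,c1:acidic:2.30;n1:basic:10.00
C,4-Hydroxyproline,PMMYEEVYMWASQN-UHFFFAOYSA-N,amino_acid,c1:acidic:1.82;n1:basic:9.65
D,Ornithine,AHLPHDHHMVZTML-BYPYZUCNSA-N,amino_acid,c1:acidic:1.94;n1:basic:8.65;n2:basic:10.76
E,Arginine,ODKSFYDXXFIFQN-BYPYZUCNSA-N,amino_acid,c1:acidic:2.17;n1:basic:9.04;n2:basic:12.48
F,Citrulline,RHGKLRLOHDJJDR-BYPYZUCNSA-N,amino_acid,c1:acidic:2.43;n1:basic:9.41
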