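"filter","initial_stage","final_stage","minor","major","appeared","vanished","none"
"R1","blastula","early gastrula",21,1,NA,1,NA
"R1","blastula","mid gastrula",1,0,NA,0,NA
"R1","early gastrula","mid gastrula",4,2,NA,0,NA
"R1","early gastrula","late gastrula",4,1,NA,0,NA
"R1","mid gastrula","late gastrula",3,0,NA,0,NA
"R1","blastula","early planula",0,1,NA,0,NA
"R1","mid gastrula","early planula",1,0,NA,0,NA
"R1","late gastrula","planula",4,1,NA,0,NA
"R1","early planula","planula",7,0,NA,0,NA
"R1","early planula","late planula",0,1,NA,0,NA
"R1","planula","late planula",9,0,NA,0,NA
"R2","blastula","early gastrula",8,0,NA,0,NA
"R2","early gastrula","mid gastrula",5,0,NA,0,NA
"R2","blastula","late gastrula",1,0,NA,0,NA
"R2","early gastrula","late gastrula",2,2,NA,0,NA
"R2","mid gastrula","late gastrula",8,0,NA,0,NA
"R2","blastula","early planula",0,1,NA,0,NA
"R2","early gastrula","early planula",1,0,NA,0,NA
"R2","mid gastrula","early planula",1,0,NA,0,NA
"R2","late gastrula","early planula",4,1,NA,0,NA
"R2","late gastrula","planula",2,1,NA,0,NA
"R2","early planula","planula",4,0,NA,1,NA
"R2","early planula","late planula",1,0,NA,0,NA
"R2","planula","late planula",3,0,NA,0,NA
"R3","early gastrula","mid gastrula",2,1,NA,0,NA
"R3","early gastrula","late gastrula",2,0,NA,0,NA
"R3","mid gastrula","late gastrula",1,0,NA,0,NA
"R3","mid gastrula","early planula",1,0,NA,0,NA
"R3","late gastrula","early planula",3,0,NA,0,NA
"R3","early gastrula","planula",0,1,NA,0,NA
"R3","mid gastrula","planula",1,0,NA,0,NA
"R3","late gastrula","planula",1,0,NA,0,NA
"R3","early planula","planula",2,0,NA,0,NA
"R3","early planula","late planula",1,0,NA,0,NA
"R3","planula","late planula",1,1,NA,0,NA
"all","blastula","early gastrula",29,3,1,1,1
"all","blastula","mid gastrula",1,0,2,0,0
"all","early gastrula","mid gastrula",12,3,0,0,1
"all","blastula","late gastrula",1,0,0,0,0
"all","early gastrula","late gastrula",8,3,2,0,0
"all","mid gastrula","late gastrula",12,0,1,0,0
"all","blastula","early planula",0,2,0,0,0
"all","early gastrula","early planula",1,0,1,0,0
"all","mid gastrula","early planula",4,1,4,0,0
"all","late gastrula","early planula",8,2,1,0,0
"all","early gastrula","planula",0,3,3,0,0
"all","mid gastrula","planula",2,0,3,0,0
"all","late gastrula","planula",7,2,2,0,0
"all","early planula","planula",17,0,0,1,0
"all","mid gastrula","late planula",0,2,1,0,0
"all","early planula","late planula",2,1,0,0,0
"all","planula","late planula",16,2,0,0,0
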