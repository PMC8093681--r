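species,genus,guild,abundance
sp001,Gen5,G,181
sp002,Sing2,X,143
sp003,Gen6,G,122
sp004,Sing4,X,104
sp005,Gen1,G,100
sp006,Sing6,X,84
sp007,Sing7,X,79
sp008,Gen2,G,74
sp009,Sing9,X,66
sp010,Gen1,G,62
sp011,Gen4,G,62
sp012,Sing12,X,43
sp013,Sing13,X,42
sp014,Gen3,G,34
sp015,Sing15,X,32
sp016,Sing16,X,28
sp017,Sing17,X,28
sp018,Gen2,G,21
sp019,Sing19,X,21
sp020,Gen3,G,19
sp021,Sing21,X,15
sp022,Sing22,X,14
sp023,Sing23,X,11
sp024,Gen4,G,11
sp025,Sing25,X,10
sp026,Sing26,X,9
sp027,Sing27,X,9
sp028,Sing28,X,7
sp029,Sing29,X,6
sp030,Sing30,X,5
sp031,Sing31,X,3
sp032,Sing32,X,3
sp033,Sing33,X,3
sp034,Sing34,X,2
sp035,Gen6,G,2
sp036,Sing36,X,2
sp037,Gen5,G,1
sp038,Gen6,G,1
sp039,Sing39,X,1
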