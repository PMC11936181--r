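scheme,rank,compound_id
score1,1,Rutaecarpine
score1,2,Sesamolin
score1,3,Corilagin
score1,4,Apigetrin
score1,5,Gamabufotalin
score1,6,Protopine
score1,7,5-methoxyflavone
score1,8,"7,3',4'-trihydroxyisoflavone"
score1,9,Viaminate
score1,10,KAN0438757
score2,1,Sesamolin
score2,2,Rutaecarpine
score2,3,Corilagin
score2,4,Apigetrin
score2,5,Gamabufotalin
score2,6,Protopine
score2,7,Viaminate
score2,8,5-methoxyflavone
score2,9,"7,3',4'-trihydroxyisoflavone"
score2,10,Savinin
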