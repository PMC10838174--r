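>trn01_cloverleaf
ACUCAAUUAGAAUUUUUUAAUUCUUCUAAUUAACUUAUAGAGCAACUUUUAUUUUGUAUUGAGUU
(((((((..(((........))).((((.........))))...((.........))))))))).
>trn02_cloverleaf
CUCAAGUGCCAAGAUAAAUACUUGGUGUCUCUUAAUAACUGAGACUUAUUGACAAUUUCUUCCUUGAGA
((((((..(((((.......))))).(((((.........))))).....((........)))))))).
>trn03_cloverleaf
ACUUAUUAAUCUGGUAUCUCUCGGAUUCAUUCAUGAAUAUAGGGAGUGAUAUUCCGUUUAAAUUUAUGAAUAAGUA
(((((((..(((((......))))).((((((...........)))))).....(((........)))))))))).
>trn04_cloverleaf
AUUGAGACUGAGUAUAAUCUCAUUUUCUUUUAUAGAAAAGUAACACUACAGUCUCAAUA
((((((..((((......)))).((((.......))))....((......)))))))).
>trn05_cloverleaf
AAUUGGCAUAAAAAUAAGAGUUACCCUUUAGAACUCAAUAUUAAUUAAGUUAUUCCAAUUU
((((((..((....)).(((((.........)))))......((........)))))))).
>trn06_cloverleaf
UAGCCACGUGCUUAUUACAUAAAGUUUCUUCACUUCAUAUACGGAGAAAAAGGUAAAAAUAUGUCUGUGGCUAU
(((((((..((((........)))).(((((...........)))))...(((((......)))))))))))).
>trn07_cloverleaf
CAAGCGGGAAGAUUUCUUUAUAUCAAAUAAUAAUAUUUUCUGAAGGUACAACUUCCGCUUGC
((((((..(((....))).((((.........)))).....((((......)))))))))).
>trn08_d_armless
UUAAAAGAUUAUUCUAUGAGAUUCCUACUCUCAUUUUAGGUAUUGGCCCUUUUAAU
(((((((........((((((.......))))))....((......))))))))).
>trn09_d_armless
AGUUUAAAAAUUAAUUGUUGAAUUAGAACUUCGACAUUCUAUUAUAAUAUUAUUAUAUUGAGCUU
(((((((........((((((.........))))))......(((.........)))))))))).
>trn10_d_armless
GCAGUAUAUAACAAGACAAAUUUUUAUUUUUUGUCAUAUUUAUUACUAAAUAUUGUAAUUACUGCG
((((((........(((((...........)))))......(((((........))))))))))).
>trn11_d_armless
UAUAUUUUAAGAUAAUUAUAAAUAAUAAAUAAAAAUGCCAAUCGUGAGUGGCAAAUAUAU
(((((((........((((.........))))....((((........))))))))))).
>trn12_d_armless
GUGAUGUAAGUAUCAAUAUUGCUUUUUAAUAUGUAUUGUUUUUUCCUAAGAUACAUUACU
(((((((........((((.........)))).....(((((.....)))))))))))).
>trn13_d_armless
AUGAGAAAAAUGGUUCUACUAUAUAGGUUUGUAGACAGUUGCAUUUGUUGCAUCUCAUC
((((((........(((((...........)))))....((((.....)))))))))).
>trn14_d_armless
CAUGUACCAUUAGUAACUUACAUAUAUUCAAUGUAAGUUUUUUUAUGGUAUUUUUGCCAUAGUACAUGA
(((((((........((((((...........)))))).....(((((........)))))))))))).
>trn15_t_armless
UGGUGAAUUUCUAUAUACUUAGGAAUUUGUUUCAUUCAAAUUCUUUACCGA
((((((..((((........)))).((((.......))))....)))))).
>trn16_t_armless
UCAGUUCUUAAUUUAUAUUCUAUUAGUAAUAUAGAUGUAAACUGAA
((((((..((.....)).(((((.......)))))....)))))).
>trn17_t_armless
AUGCAGUACUAACUUAUUUAGUUAUAAGAAUAUUUAUGUCUUAUUAACUGCAUU
(((((((..(((((.....))))).((((.........))))....))))))).
>trn18_t_armless
CAAUAUAAUGUCAAUUGGCACGUAUAAUUAAUAUAUUGUUUAUGUUGU
((((((..((((....)))).((((.......)))).....)))))).
>trn19_t_armless
GAGUCUUUAUCAUUUGAUUAUCACAGUAAAAAACUGUGAUAUGAGAAGACUCG
((((((..(((....))).(((((...........)))))......)))))).
>trn20_t_armless
UAUUGAAACAUAUAUUCUGCUAUGUAUAAAAAUAAAAUUUAUUUUUCAAUAU
((((((..((((........)))).((((.........))))...)))))).
>trn21_t_armless
UUAUUAUCAUGAGUAAAAUAGAUUUUAAUAAAAAAAAAAAGUUAAGUGUAAUAAU
(((((((..((.......)).(((((...........))))).....))))))).
>trn22_minimal
UUAUUAUUACUUAUUAUCCUUUAAAUGAGGAUUAAAUAAUAAU
(((((((........((((.........))))...))))))).
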