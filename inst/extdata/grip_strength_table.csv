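study,n,pronation_extension,pronation_neutral,pronation_flexion,neutral_extension,neutral_neutral,neutral_flexion,supination_extension,supination_neutral,supination_flexion,note
Bhardwaj2011,100,,,,107,100,54,,,,wrist immobilized at 30 deg flexion/extension
Parvatikar2009,50,,,,91,100,,,,,shoulder 0 deg elbow 90 deg
Mogk2003,10,95,87,50,99,100,56,98,94,61,peak force as 100% MVC
Fong2001,30,,,,102,100,,,,,
Claudon2003,15,93,84,62,104,100,73,103,101,71,maximal voluntary flexion/extension; neutral-ext at 30 deg
DeSmet2004,40,,92,,,100,,,101,,non-immobilized wrist full pronation/supination
Kattel1996,15,,,,,100,73,,,,shoulder 0 deg elbow 90 deg; flexion at 2/3 max
Richards1996,106,,91,,,100,,,102,,
Zellers1992,20,,,,98,100,84,,,,full voluntary flexion
Duque1995,20,,,,,100,52,,,,elbow at 90 deg flexion
Marley1996,20,,80,,,100,,,90,,
Terrell1976,40,69,88,57,77,99,70,77,100,73,wrist at 50 deg extension
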