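fixture,learning_rate,round,epsilon,alpha
11,0.5,1,0.22500000000000003,0.30919065678723168
11,0.5,2,0.28744017489773188,0.22696228060043824
11,0.5,3,0.34169291772925964,0.16393977012725797
11,0.5,4,0.30033515573780212,0.21142559740315706
11,0.5,5,0.37162013863984783,0.13131816462727619
11,0.5,6,0.33980432878559941,0.16604157856143595
11,0.5,7,0.35436159452673316,0.14998043948689713
11,0.5,8,0.41001827742845887,0.090972454982268774
11,0.5,9,0.42183294188017534,0.078813372866203643
11,0.5,10,0.42409581027468768,0.07649547806094209
11,0.5,11,0.43049318719830487,0.069959811793448332
11,0.5,12,0.34921533551133455,0.15562251796182358
11,0.5,13,0.41248270519023461,0.088427851368716046
11,0.5,14,0.45389548804049673,0.046235850571538867
11,0.5,15,0.43669747163352329,0.063644040904055094
11,1,1,0.22500000000000003,0.61838131357446335
11,1,2,0.23297491039426527,0.59579437256310708
11,1,3,0.3406901509705248,0.33011009429567795
11,1,4,0.30690491767528072,0.40731460425353083
11,1,5,0.36070087117264166,0.28616173096987224
11,1,6,0.35717007960975505,0.29383404897169224
11,1,7,0.33860245840417297,0.33476417670055519
11,1,8,0.3005651992736425,0.42230394081348593
11,1,9,0.39190356659466591,0.21965883551114845
11,1,10,0.36219664964510945,0.28292135607789476
11,1,11,0.43445886234161651,0.13184088824020102
11,1,12,0.38970217947834662,0.22428213167396674
11,1,13,0.38478118718377297,0.23465158499145047
11,1,14,0.4532204200019585,0.093833587042921718
11,1,15,0.43591195743549283,0.12888502634118934
22,0.5,1,0.22500000000000001,0.30919065678723173
22,0.5,2,0.26647726153774665,0.25314241991135361
22,0.5,3,0.24923112392952287,0.27567929375013561
22,0.5,4,0.25023827645500774,0.27433547108676748
22,0.5,5,0.30171391704611289,0.20978740147480746
22,0.5,6,0.29381657924922555,0.2192298284934131
22,0.5,7,0.32749248673136122,0.17988704250659895
22,0.5,8,0.38235871765941043,0.11988715505167769
22,0.5,9,0.31117151957205147,0.19866200752977459
22,0.5,10,0.35731716699197108,0.14675688274230506
22,0.5,11,0.4114730703018219,0.089469777584650287
22,0.5,12,0.30674913353739769,0.20384041885448365
22,0.5,13,0.3077132499129438,0.20270797649590003
22,0.5,14,0.30245667890653893,0.20890664096809591
22,0.5,15,0.38775462445967179,0.11419010355050196
22,1,1,0.22500000000000001,0.61838131357446346
22,1,2,0.19354838709677427,0.71355817782007258
22,1,3,0.25388888888888894,0.53898890281451628
22,1,4,0.20774385703648554,0.66928944404011181
22,1,5,0.28908596482087789,0.44991370778180473
22,1,6,0.24131825893634065,0.57273286858839123
22,1,7,0.29767947951500395,0.42918627307306889
22,1,8,0.2807281676729686,0.47042626498551149
22,1,9,0.29078892653057287,0.44577776125190843
22,1,10,0.31464131215648267,0.38925451732306748
22,1,11,0.41109199915116196,0.17972647214236731
22,1,12,0.28041072647349552,0.4712125935951928
22,1,13,0.35439763409245895,0.29988211935822212
22,1,14,0.3798320604327628,0.24513055141315215
22,1,15,0.34826322625688438,0.31334108400814131
33,0.5,1,0.17500000000000002,0.38764935310279169
33,0.5,2,0.25252225879418666,0.27130128217498467
33,0.5,3,0.26931846034826662,0.24952079192659679
33,0.5,4,0.31061490742814618,0.1993115312328278
33,0.5,5,0.25584595572680591,0.26691813355844557
33,0.5,6,0.26852980754371825,0.25052363706512482
33,0.5,7,0.25311194674043391,0.2705208610091297
33,0.5,8,0.34713794570888556,0.15791090469333766
33,0.5,9,0.38198565929930034,0.1202821488512974
33,0.5,10,0.27557890845821087,0.24162470869853953
33,0.5,11,0.37560778772537851,0.127058308754291
33,0.5,12,0.36827508517348195,0.13490596626621706
33,0.5,13,0.38587595411976294,0.11617024535751862
33,0.5,14,0.39638312963234718,0.10513960837113634
33,0.5,15,0.29787083965626499,0.21436435190442826
33,1,1,0.17500000000000002,0.77529870620558339
33,1,2,0.22294372294372289,0.6242967001293217
33,1,3,0.19916434540389971,0.69576270526872153
33,1,4,0.22572393414943021,0.61630788096919054
33,1,5,0.26718171838828597,0.50448437027334958
33,1,6,0.20240597367176638,0.685662138947427
33,1,7,0.29204871927091108,0.44272732181370278
33,1,8,0.25069996220178636,0.54744131671071194
33,1,9,0.3757740503008774,0.25376218449802207
33,1,10,0.26405974291703638,0.51248678325992281
33,1,11,0.30324835433103059,0.41593845362237902
33,1,12,0.32305948624349085,0.36987346371457808
33,1,13,0.33286411875432403,0.34762969513009451
33,1,14,0.41643356269559767,0.16871568484403421
33,1,15,0.36317144166548343,0.28081273314771277
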