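gene	known_origin	category	expressed	has_snps
AF357425	MATERNAL	ok	TRUE	TRUE
AK050713	MATERNAL	ok	TRUE	TRUE
Asb4	MATERNAL	ok	TRUE	TRUE
Cdkn1c	MATERNAL	ok	TRUE	TRUE
Grb10	MATERNAL	ok	TRUE	TRUE
H19	MATERNAL	ok	TRUE	TRUE
Igf2r	MATERNAL	ok	TRUE	TRUE
Meg3	MATERNAL	ok	TRUE	TRUE
Mirg	MATERNAL	ok	TRUE	TRUE
Rian	MATERNAL	ok	TRUE	TRUE
Rtl1as	MATERNAL	ok	TRUE	TRUE
Airn	PATERNAL	ok	TRUE	TRUE
Blcap	PATERNAL	ok	TRUE	TRUE
D7Ertd715e	PATERNAL	ok	TRUE	TRUE
Igf2	PATERNAL	ok	TRUE	TRUE
Igf2as	PATERNAL	ok	TRUE	TRUE
Impact	PATERNAL	ok	TRUE	TRUE
Kcnq1ot1	PATERNAL	ok	TRUE	TRUE
Mest	PATERNAL	ok	TRUE	TRUE
Ndn	PATERNAL	ok	TRUE	TRUE
Nespas	PATERNAL	ok	TRUE	TRUE
Nnat	PATERNAL	ok	TRUE	TRUE
Peg10	PATERNAL	ok	TRUE	TRUE
Peg12	PATERNAL	ok	TRUE	TRUE
Peg13	PATERNAL	ok	TRUE	TRUE
Peg3	PATERNAL	ok	TRUE	TRUE
Plagl1	PATERNAL	ok	TRUE	TRUE
Sgce	PATERNAL	ok	TRUE	TRUE
Slc38a4	PATERNAL	ok	TRUE	TRUE
Snrpn	PATERNAL	ok	TRUE	TRUE
Snurf	PATERNAL	ok	TRUE	TRUE
Zdbf2	PATERNAL	ok	TRUE	TRUE
Dlk1	PATERNAL	ok	TRUE	TRUE
tsImp01	MATERNAL	ok	TRUE	TRUE
tsImp02	PATERNAL	ok	TRUE	TRUE
tsImp03	MATERNAL	ok	TRUE	TRUE
tsImp04	PATERNAL	ok	TRUE	TRUE
tsImp05	MATERNAL	ok	TRUE	TRUE
tsImp06	PATERNAL	ok	TRUE	TRUE
tsImp07	MATERNAL	ok	TRUE	TRUE
tsImp08	PATERNAL	ok	TRUE	TRUE
tsImp09	MATERNAL	ok	TRUE	TRUE
tsImp10	PATERNAL	ok	TRUE	TRUE
tsImp11	MATERNAL	ok	TRUE	TRUE
tsImp12	PATERNAL	ok	TRUE	TRUE
tsImp13	MATERNAL	ok	TRUE	TRUE
tsImp14	PATERNAL	ok	TRUE	TRUE
limImp01	MATERNAL	ok	TRUE	TRUE
limImp02	PATERNAL	ok	TRUE	TRUE
limImp03	MATERNAL	ok	TRUE	TRUE
limImp04	PATERNAL	ok	TRUE	TRUE
loExp01	MATERNAL	ok	FALSE	TRUE
loExp02	PATERNAL	ok	FALSE	TRUE
loExp03	MATERNAL	ok	FALSE	TRUE
loExp04	PATERNAL	ok	FALSE	TRUE
loExp05	MATERNAL	ok	FALSE	TRUE
loExp06	PATERNAL	ok	FALSE	TRUE
loExp07	MATERNAL	ok	FALSE	TRUE
loExp08	PATERNAL	ok	FALSE	TRUE
loExp09	MATERNAL	ok	FALSE	TRUE
loExp10	PATERNAL	ok	FALSE	TRUE
loExp11	MATERNAL	ok	FALSE	TRUE
loExp12	PATERNAL	ok	FALSE	TRUE
loExp13	MATERNAL	ok	FALSE	TRUE
loExp14	PATERNAL	ok	FALSE	TRUE
loExp15	MATERNAL	ok	FALSE	TRUE
loExp16	PATERNAL	ok	FALSE	TRUE
loExp17	MATERNAL	ok	FALSE	TRUE
loExp18	PATERNAL	ok	FALSE	TRUE
loExp19	MATERNAL	ok	FALSE	TRUE
loExp20	PATERNAL	ok	FALSE	TRUE
loExp21	MATERNAL	ok	FALSE	TRUE
loExp22	PATERNAL	ok	FALSE	TRUE
loExp23	MATERNAL	ok	FALSE	TRUE
loExp24	PATERNAL	ok	FALSE	TRUE
loExp25	MATERNAL	ok	FALSE	TRUE
loExp26	PATERNAL	ok	FALSE	TRUE
loExp27	MATERNAL	ok	FALSE	TRUE
loExp28	PATERNAL	ok	FALSE	TRUE
loExp29	MATERNAL	ok	FALSE	TRUE
loExp30	PATERNAL	ok	FALSE	TRUE
loExp31	MATERNAL	ok	FALSE	TRUE
loExp32	PATERNAL	ok	FALSE	TRUE
loExp33	MATERNAL	ok	FALSE	TRUE
loExp34	PATERNAL	ok	FALSE	TRUE
loExp35	MATERNAL	ok	FALSE	TRUE
loExp36	PATERNAL	ok	FALSE	TRUE
loExp37	MATERNAL	ok	FALSE	TRUE
loExp38	PATERNAL	ok	FALSE	TRUE
loExp39	MATERNAL	ok	FALSE	TRUE
loExp40	PATERNAL	ok	FALSE	TRUE
loExp41	MATERNAL	ok	FALSE	TRUE
loExp42	PATERNAL	ok	FALSE	TRUE
loExp43	MATERNAL	ok	FALSE	TRUE
loExp44	PATERNAL	ok	FALSE	TRUE
loExp45	MATERNAL	ok	FALSE	TRUE
loExp46	PATERNAL	ok	FALSE	TRUE
loExp47	MATERNAL	ok	FALSE	TRUE
loExp48	PATERNAL	ok	FALSE	TRUE
loExp49	MATERNAL	ok	FALSE	TRUE
loExp50	PATERNAL	ok	FALSE	TRUE
loExp51	MATERNAL	ok	FALSE	TRUE
loExp52	PATERNAL	ok	FALSE	TRUE
loExp53	MATERNAL	ok	FALSE	TRUE
loExp54	PATERNAL	ok	FALSE	TRUE
loExp55	MATERNAL	ok	FALSE	TRUE
loExp56	PATERNAL	ok	FALSE	TRUE
loExp57	MATERNAL	ok	FALSE	TRUE
loExp58	PATERNAL	ok	FALSE	TRUE
loExp59	MATERNAL	ok	FALSE	TRUE
loExp60	PATERNAL	ok	FALSE	TRUE
loExp61	MATERNAL	ok	FALSE	TRUE
noSnp01	MATERNAL	ok	TRUE	FALSE
noSnp02	PATERNAL	ok	TRUE	FALSE
noSnp03	MATERNAL	ok	TRUE	FALSE
noSnp04	PATERNAL	ok	TRUE	FALSE
noSnp05	MATERNAL	ok	TRUE	FALSE
smallRna01	MATERNAL	small_rna	TRUE	TRUE
smallRna02	PATERNAL	small_rna	TRUE	TRUE
smallRna03	MATERNAL	small_rna	TRUE	TRUE
smallRna04	PATERNAL	small_rna	TRUE	TRUE
smallRna05	MATERNAL	small_rna	TRUE	TRUE
smallRna06	PATERNAL	small_rna	TRUE	TRUE
smallRna07	MATERNAL	small_rna	TRUE	TRUE
smallRna08	PATERNAL	small_rna	TRUE	TRUE
smallRna09	MATERNAL	small_rna	TRUE	TRUE
smallRna10	PATERNAL	small_rna	TRUE	TRUE
smallRna11	MATERNAL	small_rna	TRUE	TRUE
smallRna12	PATERNAL	small_rna	TRUE	TRUE
smallRna13	MATERNAL	small_rna	TRUE	TRUE
smallRna14	PATERNAL	small_rna	TRUE	TRUE
smallRna15	MATERNAL	small_rna	TRUE	TRUE
smallRna16	PATERNAL	small_rna	TRUE	TRUE
smallRna17	MATERNAL	small_rna	TRUE	TRUE
smallRna18	PATERNAL	small_rna	TRUE	TRUE
smallRna19	MATERNAL	small_rna	TRUE	TRUE
smallRna20	PATERNAL	small_rna	TRUE	TRUE
smallRna21	MATERNAL	small_rna	TRUE	TRUE
smallRna22	PATERNAL	small_rna	TRUE	TRUE
notGenuine01	MATERNAL	not_genuine	TRUE	TRUE
notGenuine02	PATERNAL	not_genuine	TRUE	TRUE
notGenuine03	MATERNAL	not_genuine	TRUE	TRUE
notGenuine04	PATERNAL	not_genuine	TRUE	TRUE
notGenuine05	MATERNAL	not_genuine	TRUE	TRUE
notGenuine06	PATERNAL	not_genuine	TRUE	TRUE
notGenuine07	MATERNAL	not_genuine	TRUE	TRUE
notGenuine08	PATERNAL	not_genuine	TRUE	TRUE
notGenuine09	MATERNAL	not_genuine	TRUE	TRUE
notGenuine10	PATERNAL	not_genuine	TRUE	TRUE
notGenuine11	MATERNAL	not_genuine	TRUE	TRUE
notGenuine12	PATERNAL	not_genuine	TRUE	TRUE
A19dup	MATERNAL	duplicate	TRUE	TRUE
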