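ref_id	gene_name	locus_id	family	role	sites	sequence
REF_moxA	moxA	CAJ19378	MCO	POSITIVE	T1:15=H;T1:45=C;T1:75=H;T1:105=MLF;T2:135=H;T2:165=H;T3a:195=H;T3a:225=H;T3b:255=H;T3b:285=H	VSDYGYMRPLGGTIHSFWINHGRAVILIQISDSGVTNAFKPRNECNLSFTSFKGLAVYRKHVSIRVGNLQIPIIHYQKNMKTKIFGTAGAGLRQNNSKPDRIVWMGASYDCFIKALFASRWSSGFSFGGDDLLRHDDICESDGVFSGFADREISKGELVDVYRNHKLIFIRPQKIYRFDYVGYSQGFFMESKAHHDAPVEVGEVGEDAVFMANMPVRMMIVAIEHEVLKQIDIRKTTEKSVDYAKGKASMNHKDHAVAIHEVVNTALFRALAITVGVGSNLEYVHAAAAGGACIETAALH
REF_mcoA	mcoA	ABY98562	MCO	POSITIVE	T1:15=H;T1:45=C;T1:75=H;T1:105=MLF;T2:135=H;T2:165=H;T3a:195=H;T3a:225=H;T3b:255=H;T3b:285=H	VIDYGYMRAIGGTIHSFWLNHGRAVILRQISDSGPTNAFKPRNECNLSFTSQKGLAVERKHVLIRVSNLQIPIIHYQDNMKTKIFGTAIAGLEQNNSKPDRKVWMGASHDCWIKALFASRWSSGFSEGGDDLLRHDDECETDGVFSGFGQREISSGELVGVFKDHKLIFIRPQQIYRFDYVKYSQGFFMETKAHHDAIVNVGEVGEDAEFMANMPVRMLIVAIEHEVLKQIAARKPIEKSVDYAKGKQSMNHSDHAVSIHEVVGTSLFRGLAIAVGVSANLDYIHQHAAGGACIEEAALH
REF_mnxG	mnxG	PputGB1_2447	MCO	POSITIVE	T1:15=H;T1:45=C;T1:75=H;T1:105=MLF;T2:135=H;T2:165=H;T3a:195=H;T3a:225=H;T3b:255=H;T3b:285=H	VIDYGYVRRLGGTIHSFWINHGRAVILIQISDSGPDNAFKPRQECNLSFTDQKGLAVERKHVSIRVSNLQIPIIHYQKNMQTKIFGTAGAGLRQNNSKPDRSVWMGALHDCFIHALFASRWSSGFSEGGDDLLRHDDECETDAVFSGFAQREISSGELVGVYKNHKLIFIRPQKIYRFDYVGYSQGSFMEDKAHHDAPVNVGEVGEDAVFMANMPVRMSLVAIEHEVLKKIAIRKTTEKSVDYAKGKQSQNNSDHAVSIHEVVGAALFRALALAVGVGSSLEYIHAIAAGGACIETAAVH
REF_neg1	mcoX1	SYN_NEG1	MCO	NEGATIVE	T1:15=H;T1:45=C;T1:75=H;T1:105=MLF;T2:135=H;T2:165=H;T3a:195=H;T3a:225=H;T3b:255=H;T3b:285=H	VIDYGQERRIGGTIASLWFNHGSDVDTVQISLEGPLNAGKVRQEASKSFYGVKGLALERKHVDIRVTALTVEVIAYQSNMKTAGYGTAGAGHRQTNSKPSRILWAGVCYRPFISLLFAPRWSPCFENGGLDLLRADDELETPGVPIGRAKYSISKGTLVSVYKAAKLIVFRPGKIYRFDYAGYSQGFFMETKAHADAPDSVGDLEEDSVKMANMWVRVVPVAIAATVLKQRAIRETTNKRANYAEGKMSHEHTDAAVSIHEVIVTALFKGLAILVGAASNLEYIAASAASGGCMEVEAVN
REF_neg2	mcoX2	SYN_NEG2	MCO	NEGATIVE	T1:15=H;T1:45=C;T1:75=H;T1:105=MLF;T2:135=H;T2:165=H;T3a:195=H;T3a:225=H;T3b:255=H;T3b:285=H	VIDYAYVLDLGNPIASDTINIGAAVILAQIKSAGRTKACKKDNEAALSYTSQKNLFVSRAHVNIRTSKLQIPQIAYQKNMKGQILGQPGAGLRQNNSKPFHVGWAGASHICEAKALFASRASSELSVGGDDLLRADNKCEGDGVFSGFVQRAISMAELVGVYKNAKIIFFRPREVYRFTMIGYDGAFFIETKAHADLPVNVGGVGEDLLICAAMPFRLVIDALEAKVLKHIMDHKTTEKDADYTMGKASIPYTDALVSALEVLNTKIFRKLLIAAKVGENLEAIAAIAKGGECIETASLS
REF_out	out	SYN_OUT	MCO	OUTGROUP		SGLPSLIIGGVVYNAFKGLLVGVYMSAGGSLNDCQTAAIWHEGHFYRLLMYSNGVEGEIENKVHLQKRNVAYKFAIEVSKSKVRGPPDELKRLQALNLINAIITIKVMTYHFPNYPIQNGAMKLCLSKIFVRNFCERVKDCCGKQTITAYYALIIREIIDLKVALLCNLELNFLPQKRKINTHDLFYTDDIEYVPTYVIYNERHVIMKDNSQTARNGQSIWFSVIVNKRGVHASNIELTEIGLIEIWLLTADLRIGHLKCKHLIELQKWSYLGIVEFMSADWLYISGIGRGYIHSDFGVQ
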