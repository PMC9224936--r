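>pos001 synthetic true positive
PSDYGDMRPLPGTFHQFWINHGRALILLQISESGVTNAFKPRNECNLSFTSFKGLYVYRKHVSIRVGNLQQPIFHYMKRV
KTKIFITAGAGLRQNNSKPSAIVWMGASYDCIIRALFASRWQAGFYFGGDDLLRHDSICESDGVMSGFADREIRKGELVD
VYANHKLIFIRPPKIYYFDYVGYSRGLFVEFKAHHDVHVEVGELGEDEVFMTNMPVRVMIVAIEHETLKQIDIQKTTERS
VQYAVGKASMNHKDHAIAIHEVVNTALFRALAIIAGVGFSPEYVHAAAAGGACIETALLH
>pos002 synthetic true positive
VIIYGYMRAIGGTIHSFWINHGRAVILRQISDSGETNGFQPDSACNLSFTSQKGLAFERKHVLILVENIQIPIIHYQDRM
KTQIFGTAIAGLEVNASKPDRKVWMGASDDCWIKFLFADRYHSGHSEGGDDLLRHDDECETDGYFSGFGQREISSGQLVG
VLKDHKLIYIRPQQIYRFDYVKYHQGYFMETKAHHDAIANLGEVGEDAEFMANIPVRMLIVAIEHEVVKQIAARKPIEKT
VDYAKEKQSMNHSDHAVSVHEPLGTSLFKGLAIAAGVSAGLDYIHQYAAGGACIEEAALH
>pos003 synthetic true positive
VVGYGYVLRLGGTIHSFWINHGRAVILIQIGDSGPDNAFQPRRECNLSFTDQKGLAVERKHVSLLVKNLQIPIIHYQKNM
KAKIFGTANAGLRQNNSKPDRSVWMGALHICFIHALFAIRWSSGFSEGYMDLLRHDDKCEMDAVFSGFAQREKSNGELVG
VYKNHKLIFIRPQDIYQFDKVGYSQGAFMEDKAHHEAVVPVGEVGEDAVFVANLPVRHSLVAIEHEVLKKIAIRKTTEKS
VDYAKGKQVMNNEDHAVSIHEVVGAALFRALSLAVGAGSSLEYLHFIAAGGACIETAALF
>pos004 synthetic true positive
VSDGGYMRPLGGTLHAFWINHGRAVILIQISDQGRTNAFPPRNECNLSFTSFKGLAIYRKHVSIRVGNLQEPIIHYQKNM
KFSIYGTAGAGLRQNNSKPDKIVLMGASYDCFIKALFVQRWASGFSGGGDDLLRHDDICEGCGVFSGFADREISNGELVD
DFRNHKLMFIRPQKIYRFDYVGYSQGYFMEVKAHHDAPVEIGEVKEDAVFVANMPVRMMIVGIEHENLKQIDTRKTTEKQ
CDYAKGKASMNDKDHAVRIHEVENTAMFRALGITVGVGGNLEYVHAAAAGGACIETAASH
>abl001 synthetic site-ablated decoy
PSDYGDMRPLPGTFAQFWINHGRALILLQISESGVTNAFKPRNEANLSFTSFKGLYVYRKHVSIRVGNLQQPIFAYMKRV
KTKIFITAGAGLRQNNSKPSAIVWAGASYDCIIRALFASRWQAGFYFGGDDLLRADSICESDGVMSGFADREIRKGELVD
VYANAKLIFIRPPKIYYFDYVGYSRGLFVEFKAHADVHVEVGELGEDEVFMTNMPVRVMIVAIEAETLKQIDIQKTTERS
VQYAVGKASMNHKDAAIAIHEVVNTALFRALAIIAGVGFSPEYVAAAAAGGACIETALLH
>abl002 synthetic site-ablated decoy
VIIYGYMRAIGGTIASFWINHGRAVILRQISDSGETNGFQPDSAANLSFTSQKGLAFERKHVLILVENIQIPIIAYQDRM
KTQIFGTAIAGLEVNASKPDRKVWAGASDDCWIKFLFADRYHSGHSEGGDDLLRADDECETDGYFSGFGQREISSGQLVG
VLKDAKLIYIRPQQIYRFDYVKYHQGYFMETKAHADAIANLGEVGEDAEFMANIPVRMLIVAIEAEVVKQIAARKPIEKT
VDYAKEKQSMNHSDAAVSVHEPLGTSLFKGLAIAAGVSAGLDYIAQYAAGGACIEEAALH
>far001 synthetic distant homolog
SIRYPYSRKLGGAVHSHLVKFHGAILIIQIADSKPFSSFRPRNEHEVPFTVTEGLFVEAKHEMKAVAKDEIYIARYQPRM
QTKIFGSSGARYRQNCSQLTRIVWLGASRECFIRAMFFRHWTIGFEKFWPLLMKEEREGDGLGMFRGFAMVEVQSGEVVG
IYKNHKLVFIAPRQDYRGDVVGLKCAWFVYTPQHHSIPRGLLEVGKDLVYTLNLPVAMIIVQIEAKLTEEAAIRKTKDRE
VQYAVSRAKILDHDHAILIHDGIDQALFRAFGVAVGCGCNVESIHNIRRGDNCMDTALRT
>far002 synthetic distant homolog
TDKFGRMRDMGGTLHDEWVVGGKAPIIIQLGDVGPSNLFKKKYECNISITDQRPIAVARTGCMITTVGIMIRYIFLKHQM
TDKILGGAQAGLRKKVLDDDAVVWLSASRDCFDGTKFRKKAFNGISEGLEDSLRHEEECATDMVRKGAAQRELKSFELVG
LYIYTKLIFILPEECYPFQRCGWINGFFYGASFHHDAPFNMLNIEEDAVYIADMPVRLVIYSVLHEDERQIAIAKLTHKS
LDLAKLKVSVLHVPHAKEIHEVVNCGAYRILAIALGLPNRLEYVHLIQADGSIIKMAAVH
>shf001 synthetic shuffled decoy
YSLCHYDHERARIYLMFVHGALSKDHRKNIQIFAVVQAENYGVMPDIKGLQKNYVLFGIKTIPAERWSDDTPLRGYNINH
NKTFEGSIWDFARVIQATIDSTGTEVIIPYKENKGRVPQRFVEIFHLAEALFVHRAVLNHTSLVQMSVESSMSGGIMPPA
QKGEIKHLFGQAHVEPCGPLDFYAKIKGIMTHGVMISDGNFAAEVLIESHGRHYAMHCEDRALGRDGSIVYLGLYVLRRA
DDAEDNWTTAPRYIFVVNVSRVFFAKCGASFVAIAGSEVFALATKARLLIGHYISKFGFQ
>shf002 synthetic shuffled decoy
SSTTAYGRLEFVKSALHVTAEIKDYTCESILPVVDQSFVPFIKILNALSDRSHDPSATAKQGAWNGFWGPEKIIDIPRYR
QQDIIACAERVGDHHQHDFYFIDGVIGDMYKNNIGKGFLEADGGVIIMGIHRKARGNKAKMAVGQEDSLAFLESIYGTMD
HCKGIMHAAVHHYQNLYFAYVELCWRDGGHLVAKDQSSHIVGQFEETTLNRGAVLASIQKEKASVYKHNATRAGGQDIHA
IVQHPGHSEEMQFGAQILGIAEEESDKLYVIGSSLIAGPEVIALRDFHIFYYMRLDEILR
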