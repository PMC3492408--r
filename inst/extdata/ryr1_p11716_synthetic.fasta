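>RYR1_SYNTHETIC_STANDIN
FGDGLNGGASRFNLNLRHYHKVIVIAIREVKLHLCLCWPKDWQQLWANIITELRIEVEVG
FKSPFVNVESGCQGWWFSWAQLRFEDLTMESGLGWTRGMGCVEITDFKWYAVVIRSWLKK
ELRQEFGHGLAGPDHSGHKWLPKVEHSQCLMHKRGWSWWTEKISEDEYQDYTRCKKDIDA
EHEQFANALSDHLTFLWLVRELGCQFDWKVSSVEIGWQNDLRGAVRSLIYIWAHNEELQE
MRQTNSLEAARLVGADEGKEMKKAIGLVPLGVATRQLQEWEFTGFRWDLSKKNLKFDDLR
VHRPDLDPAAASAQGEPLAQAKNVADDRTLMVRKWGWGTERQKVWKPLDFLNNARDFGRV
LEDSLGAKEISGMSKAANESWGPTSVVFWDQANELERPQRVDVSTDSIIGNPPLEPGAVL
LASEVKGSGPPAGPALLDCLQMRLFMTPAHLFQRFLSSSPTHRYQVSVGNVWQIANWDKQ
VLVGKSSEALVNLMPKLVAAIGEQGQALQGAETERRIGSLTGMTIKDTVLTWTGPDENQN
LMIFYGWKRAAALDREIGEQWKKWGFGCRVDTEYLMAKSKSWHYKLFDWDAQENSEEARV
PWGLDGFPSGDLNTRSRGLDVPGGERDASLKEIQRVIADPNWTYIRKYLTETYGILFFAP
EPDRTMIAWNLSDDKRDDTFALTNFATIELESQLGDKFGWGGGGNGEEIAFRVWVKIGVV
VALLAAGGGIEPRMWEVVIDQQRGTGKWNWRAWVWPWWGGFGPLWNNVKLESQFPECLLS
GPPNADMENYALAVSKDPEEISGYRWLPEIKRRACMRRMARRIASIRLNKNGIAYLNDAA
SWPHLTLWPTWLEIIFKGIHNGTAGWSGSIEFIFALPWPWAQRSIWWWEDGIIGWVTQTN
AEPLNVGTPVVKVKQGIKQKILKRLNMTTYFAKKEILDLYNIGYVAVSIVFSWGWGLVEG
ILAIIVYLHAKIWVSFLRIIIFANGSNKEKPKLEKTWEGAQLRTPPQDIIHLFAGIVQAP
PIFNVLDASLEGGSRAPDPQYAGRTRYHDASEVEQHGIPLKGARVRVTIQNFAVFFVKGL
YSVTIFQTGSYFPEVALPEVLQNGNTALEIQGGSYSSNNLWCGWAKAGVKIIWQKAEFYA
RLLKGRWDGHENWPSLCQVVWLMKFVAEDMQWGHKSNTAWSETGDADEGVIWAYGDGLFG
GCKWKSFMKRGGWQHNTACEASQDAWLTIDPSHNVFWHGSWQQTWLVISDISRVTQPVSI
SQRWTLCAPGSLGDMELWQTEQSAWEDTPEVGDVGDISDKAKAGEGLAILKTLLLGCSPA
LKSYQSRDFEANEGTKYEPPADLLTIIRGQLVPLNQMHQCGGPDMQTMKVRGLRGIPMKK
DANIGDFALFSSLIDESLACKTVPNSRGSFCTYINAFWSARSKAAVISTLVFILINKLNA
SIFGRLGAGTEALIAMVDVTKDPDTRALNWKPAIGLKNEKRYQILTSNQGALYAFSALSS
TVQQTYKKISHTDLVIGNLHEKGAEALWSRNWGWELRNDGVLTFLKREFIDAATDAWPAK
STKWGEAGRGAPEIVIRAAFRVWVHSMVKFLWQRGLLKAQVFWKSLDGYEGIGFLLHIGW
SIEFSIVLPTPFANEKFKSNFPKDYKSILGNAIEFGKTRTIVPREILEPMPAAVEVIPIL
LQLRTLGDYLFKLFAWVVSETDKFAPLGWPASVEKASELITFPNGNRLAARWNAAVRDLG
KYDGTDWLFSEGAKEVSNNQWKAWGDRTRTKIGRVFLVSSKAHLILPAVERAHDPLYSFH
CLTTIIWNKLILVGLAMALAVIVSLPPLEEAVTYTGSLEEAESALKGMSFPKTLLGLQLT
YGWSGCLFQRLDQDIPAAKREHGTPPSMTGKNVEQLWFEKDVNVKFDIDVMGMMQNNELV
TEYFGDVWKKSPRKQSMWEHRVFIGWDECIIIIVLWPPVWGAHWNKYPDLWSREFPKNIL
QLTAEQVVKNWKERVLFRRFISLSTWLRGETNKKTVKLKYGGAVIGITDMVLVNATALGM
PFGSHWDDVNQVERVWFTFVWIIIITAVEATNISMAYVTGESWFQEGEWKQTDLGALQRD
DQSLSRINTAAFKTSVTLHPWVKIFKVHSGWQWLTSVTVWSAIIAMLEDKDICVEVWNMF
LFTKSGPYWGEYQVTILKMYDGFQDSEGYYWDELEDKWMPTLESPGEMEGTRHMNARSRI
KDRSALSCELILPAWDISQDIGHFRVLQSHDIIFTPAAMRVDMGLGWNGLFPIWMRLYAQ
IKFLLGLWNEIQRADALQFWDLALPKYKKLNNGGICTCIFTLPVPTAIPMNSHARVHDHN
SFHSAVTNTSQFLLFSSNISYNLWWTSAKGRGGIGDLTTKGPWKMFYREAPTTSSPTFKA
KRREHFGEEPPDQPLFHRLWHWVKKWLDWSMGADLWGVFATGLALPAPWAWVVVLPHYQP
HSSNATLKLTHEAATFQFRAVLFNVIPKDFNVCACFLLEESIQFENLGDMAPEVIIYVSR
LWGGQRDYRVPWKDAGTSNQERAEFLRAHWALIFGATNWGIQIIVNRKSAYLIILKMHIN
PIVHWFNDWWARAMVNQDEQLVELLNVIAPNLEAVSLIVATASGFGVDALFPSSRLSPIL
IIGVNEQELGPTLPGLDEPNTSFTLQYGWELITKSAKGRGLYLWWSRAWRLETAIEQKRF
LQLAILASQNFIAIMKSGPHTLATPGREKIKLGFAGNIDNKTLVVFWDIVLANSFAFFTP
PFDAVSFVLATYWDSLAATQLFYFPNQWHLIGTHKAKTLKHGDNDGWGDLMLGDGDAVTQ
SLKHKGMPAGGALARKIFVDAVNDSFSPYNESNTMWKRVHLVATWDNFGGWRFSVLIPQP
DISFSPVTSTVDGYTLKFEEGWQEERPETESAYNASGLRVITFLDDTLGGLRLKYSVTEQ
GTNIAVYGINYKGGNLLTIEREAGISKAGVDDLIEPTIVLNKRKPKDLKLPDYPEASKHH
QLTYKITQAVELDWAGIVNPPGSCLDVLAIDFDGDLKLAALTAQEQAPVQYVESYIRYHG
IDYFVMHSFLGKGLKAYAGLWARITAEADIGKGIHQAIDSKQSSEASMANAPDEYFSCKT
QVKGVGQNFLLVGLGVVRHIDDERKMAMKITTKVSQAVYKIMLARTSAERKYIDSAFMFI
IGCADELHERSNMSLLIVDTELPLTTPLLQDRSAMAGEESLNTREYMIAVVTAIGYVEHV
DAVVRLIMQRLHLIRLESFDNLVHARDVYTVPSSFGLSPIPTTAECETRMLLFLTAVDWQ
GNFFKYVILAATEEGVRLIEPAHDFALGANGEAEGKVLKASEVAPNNWGSDGQKLEFHRR
IPRVNHNQFNPAAPYYPQGAMCSEETRKGPDELRMAMPKTTSNEQVPLAVQAEARFENIQ
NSLNSPDMAEARYREHRIYPKKVEMYPTNSLSRSQAQKPAGHEGESQQGRRTFLFIYRVW
RLTKENKKTIAVVKEKHEFMQFYAVTYMEHLYRAPKVQMYASGEAQDEGDGSYEAASLEN
ATYIKGQPKSIRLYTPCGSRDCRILFNAYANFSFVRLLIWYVVVQPNLEFARAVQIKVKR
QYLYFNELFEGATLRDTTNLACGVSALAERAVVASFRMTPEGRKSANDTKLKGDPATFTP
KNSRAPVKGRPCRILLTWYATSEVVFKKLFDALSFAMDDENTVKSLWPEAHAKVVEERDR
MIEKDKKPLDMSAWYARLFLKLHEFTDKAGKRYVIATEAFCGWRVTQAVTIQLYESSILT
LVLNELTEMIKNPRSIPEYWQHEWDLLRPPSQKHCKTARHARHELRDAFWYKLPWRAAPK
ELIGIELLPASVLLFLEKSKGNTRKTYGIKALFAAAGKAWALQDDFPDDYFILKMNCTIV
PEQWLELTIPKIFKELDFKTVKSGTMDTSDRQGQEIYSVKYHVEAQKNPNTFGGNWGDIV
MAYPSLRAYAIEHQTDRAESGGTALPGFNVGGVFFAYWWLDEIALGREASVAAGQGKTAF
RLRAPLFFIFKTGDVPVQTISSEADFGIFATNQPTLYRVMPEIWVADKAPWPINYSFFDK
LSGAKAALPLMEWGKGNEVAKLQRKASVTDEVMAAGLYGLYTRGRLKQWISTFQAAEQPY
FEHSDLHEKDGKPIEQTIQQQRNNSYSTIVWMPHGQNKKNLDGKGLGYYEKWVCEIALPW
SIWKFTSHRRVSTSDYHAKMIVQIQFAFDLRYVQWEKHRGLDFATIITDSKDSLKPELNI
DEIGYQWAVDETGRCEGSDPVNLDQAGIWDPTASSKAHELGKAQILLIRKIIRMMKAGKE
AALQILELADAALPCEQKLGAAEAVANAMNIGERGKILLALEPHKGQLKPIYTTESRTLS
SWTGEDLKVETSKEQSRPWPQNAYSRGWPLTEGDTDHKAYVRPEGDGNFAWFAGGAEKVN
SKPSNTTRGSGGKGGEGGSLNGEFTIFLKDLFVTKKLGVDGEEEEHAQAVHAFAKWEALD
MRQNRFGAAKQVYTLCARRPQKGEQFWFKEGFKVLKRPEWSESKVVPGVEAITAARWAQL
NPGISIFILEALVGIFITESTEGLRAFWLHGMAYQEVSSRVGEGAKGIAARYEPAWQDYY
GLNLMYAWVRLTAKLRLVDDDREIYPGQGQMGTLMPNHDTIKKFCEKTRQGLKAGEIWPL
QRPNGSMAVYQFNDDGNGAKPAWDIGFLFLAYTDPNESVWHFLRLKSIAPISWTAGYQDE
GMVQDYTPAITVITVYAGALHDAMDWCWYKEEEMPWNDNMCDQRPSRIWPIQINPPVPKD
LKPIKSKLSLGLPVGMSLNKSEILNSSMTSTFSSFTTEARRFQFQSVMVDVAFTIFEQLC
WVKDGISRSILEIAMQHSLAPITMWLQAWGKLHSVLPIEMDWWYVWMNSKVAHTTWTELD
WWRARPEGLFREGGKGVVQKSTFSSDGSSLPFHGRVNDKILDHSNLRNFMCLGERFTGIE
GVAGNCHAIDYLLGQGIETDIDEKANGVADHALWEGRFAGRAIRALKEVFRTIMMWA
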