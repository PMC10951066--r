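>P00451_synthetic_scaffold coagulation factor VIII precursor scaffold (synthetic filler outside Table 1 peptide coordinates)
PGMQDMVTFWWIDRVCNPAATRRYYLGAVELSWDYMQSDCRKNEPNLFKGKCVYKADRKL
PDHLWIDLQMHRIPDHLFNIAKPRPPWMGLLGPTFGCSAYDTVVITLKNMASHPVSLHAH
QPWYLSHTWYCSSFNLLCNGEHIEEECDGPWSLAGQWYCCCGWACPIHTWTFDAWRDLSH
VDLVKDLNSGLIGALLVPYTWHALQIEVIYKFTAQGAHYCWSHCFIRSPMLVAEFKVNSV
RWQLEHKLLVKRSARFFSQALWCKPPIYQCKRDVAKCPCSYRGAVHSIFLEGHTFLVRNH
RQASLEISPITEVIDFCILHNLGQFLLFCHISSHQHDGMEAALHDAHFPTMQWDHKSMYL
SQYCKNMSHWDRFHLWYIGMASEHPQMGQKVGIARMMIEIIVQHDADVCYHTWERLPQHC
CRDHFNRFYDTDYLPINIEQMCANSDWKDGPIIQGYAQIFFPARSMYPVDYSQRDPSADM
YVNYVHQPIAWANESMRGRLPWKAMYVMQTGRQDHTKGWNFTAVAQEEVPNKRAMVMVYA
VLIYDCLILGWRDVKFFEQCCNACATWQYYCFVGWISWIPQGKAIEANPRGGGQWFHFTI
PYHIATMWFRNHLTSKCEKLLCVWHANTRQHEQLCLCFKPNVVYCMSWYACCMYSMWHSN
PFTCKLDLLWMIATDNGPWEVTIMPDWMIDMPTCYHLCEEEHMFHMLPQDATQAWDMWLW
QLEKFECGAWPLRKLQLQLTCSFHRNRKWYSHHLMQIAYNLSSCELCTTMRSKTKLNSQR
QMCGVIIITQHSSDKWLSRHKMASPWIIDSNIHKCFRQPRKICAECWEGDPECATMWVHL
NMILNSPPASAVVGMSTGKNSSHNYTRTGLMLSWKPCENVNCIIWISSDCQIKPQMPGMY
LTWQLLTQQELGMSNCGIQASGGSYRNSTANKLMKSRVLFNIATGPEFPYKHNFLCQLNW
NRKCITNPMVCYVGMCFDTERDKYDDETKQPLLKQQLKDWRFNAPLRGWCPWVPKQLRHD
AVSIVCNLTGGHEAHSGIFIHEASMNKLRHAYFDPVCPSSLQGPDMTQQSQFRFVTFMME
IDPARGNMQIRCEESSLFHGSHFMRDNFTVNSRRPQNFKKAAWIVSIYEAWNMWPQSHIY
NGATSDQKVSSAALTTAFQYNCISILINARRNCAEDCHPEVGCDDIMLDREDEDSSNAIV
RLWISRWLSIFIYLKIDVRNGKNSWHSCCQCESVHIHDTWCKMRMNADWPFCQPIGSSLH
AWHPRYYNCKPHNMASRTIMAMFGGGEYKDSDKVWQYFGKFVERWFNYENTINYWGGVHR
DPVACKWCDAKYTECTWSSHKMPEGMSYQNEWEAFSLLCVINKRFWGNVRLSALTVDMIW
VTDQPDDRPPTFDCMQWKRQCFTNFHLERFVRAGVMRKARGMYPFSNGMPIIEDPISHRM
KTNHLREASVYWRMEYMKGYKMNWGCHYCMVHPYWTFVQHMHMHKQWDAIDIGDKERSYF
NYRQFGYVSNSNEWRKRISSTFYYLLTCKVRIHVQVNIEQYNAMTDMKYMHGSIYESQDW
SGWLYAFFNKPYLWVVDVELHYAGQSMHDLLDCIAQIVTLFWMGVDKYGKWYIDCRNCVR
GARCMMHCRKYLGYSMQHLMLGVRLIIHVRKQPRMIIHFDFVICNQKLGIGYCNDSIRKH
MDWPHQLKKPCWPFDARAKEIDFGLPQNPFKVWYRHYFIAAVERLWDYGMSSSPARWPNQ
NIFYLDKHYNRTQYVKQMLQWTWENPMDETMNWTAILSREQESGLIQWHHRVTQKMRVER
WNIRLYLGLNMMQENTTGHTPTWPDWAWNSANINRPGIDFIFYGILQPVRRNVPIWETLA
NFLRNFIAEDWYHQIHLWVKQYFASQVKHTVPGTIQGPHPFEFAQSKQQMSYTQDIFCKS
LWGRWLASNDTQDVRWIQHINGYIMDTLPGLVMAQDQRILCLILPCDSIYKIQAHFNKMS
KVWSTKKEEYKMALYNLYPGVFETVQKMYDFIQNGWWTPSEMCQQSLQCAFVGDARIYEK
TSTLWLWPTPLSENCEWDWLFTKSPQWKLARLHYSGSINAWSTKEPFSWIKVDLLAPMII
HGITCGLALHNWVSLYISQFIIMYSLDGKKWQTIGWHNFQVCDASWYGVKDKDDHVKMLM
PPIIARYIRLHPTHYSIRSTFFFIVKESEPDWLRCRFDSVDPRQPWWWEWVERDHLPNGF
ESFINKARLHLQGRSNAWRPQVNNPEHLIHNDHVQIWRTWEDLTQGVKSLLTSMYVKEFL
ISSPCNESWRLIVFEHPNQCIPLGFETGCYCVKKFSSTKLLTRYLRIHPQSWVHQIALRM
EVLGCEALCPF
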