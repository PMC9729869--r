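>CrtE_typeIII_synthetic synthetic GGPPS stand-in (type III)
MPHCCWLYIQARMYTHSKVTPYTQRRASCLCELSWKTLPSCCQEHGPEKVFPFTWEVSNWWISAYALIFV
RYHFNASVGQDDIESADNHIQGSEVTQQSVESCAWAAYVAPMQIAKIKMTPETYQLQQMHVPKPCHILRH
TFIKKILVIKKLTRCFQATWNAAFQNPKLWQIIMGCKSWVASKGILGAYRQLYSCRAVWEIFAIIMWVMW
ARTSAYGHYCGRFMMVFCGLIWMNYRHTWKDDIMDINSTGSHNMKHMHPSLFINFPYYAEQIGLLTHGEQ
NALKMCWQASGPFWHWWGSFAKSTFGNKFNIFPFTGRKFNLLAFAKMYSE
>HsGGPPS_typeIII_synthetic synthetic GGPPS stand-in (type III)
MVHEWSSKRQRPGNNHGCNFRNTSYHWFSTLAAMFFVVHWSGEAWPLNQWYKYIIGQSPGAMYMVMVAKC
SALYWASVGKDDIESADCKMLRLCCGYPPFKVFFMCECVLKEQKIGTQEGYINTRACCRCLFILLYFIIS
WIAWRLPYNWKFGHAREIPVYWCIQENECRSIAPIVPIPKLIYLAACICIWIMHLHEPKHGGIEPTTNHV
RTYPTAAKLRHGRKWFCWHVVVLKPPIVSADDSLDCKLSGYQPIWQFNKYHIRASQCEAKHIREETGMSN
FPGEQMTTERGQLYKEKTHFSMWHNEAYAEELQNTEQSMPRNQVASQQRK
>RtGGPPS_typeIII_synthetic synthetic GGPPS stand-in (type III)
MTKLLSPTISKLGWQNYRQAGVNTNLFRLFTFVRIQPIESPLMVYGHQIYLSRPMHPKHQSMHLMFCANT
NWYCCASVGQDDIESADHQVHRYPGQTPYNGMMMKGFVWVKPGVQVEMWGATTTQILEFHAKCINERYQC
HHYACYVYWQIHQIQIKKGICQYEVYPWNRMWTPVEYKFVRKTMPVNLHHYYSMHKLSHMQCVSYFPALW
PGAWSRQCMSIRPLYHMMEQTNHRENLIEHDDMLDIKIFCHYPNWMLCGGLYLMVSSRQSPGKSRRQFAM
TNMMRWPHNACYCANWTVWYHQLSIHNQYCPSVQTMFNKATNLVFVSRRN
>ScGGPPS_typeIII_synthetic synthetic GGPPS stand-in (type III)
MGETKVEYGPWVNTKEFFKGSCHGLIVTHIHAAMNGAFPYKFNHPFIILHYPEHILWCHILIACACGEMV
WMTWKGSANEDDNSETDIKKCCQFMWLQNMKNFVTCNNITLHERGQATFKWAKLFKLHKSQLWPTWPLQA
QVGLEGWHGVILSLCPLLRPTNAYQINEFMCSEYYMVWSATHNSQHFPIEMSLAQHPMLQWIGSISPKEN
MQIWATVYRCVELLNTVVNFAPKYCHFVTYDDQEDSLMHQWEQHYYSIGTQEGRESPIVLGFITQTWCMK
QNMCEKQIFAAGPERNEEIHQVYVLWSKRYAVALVEKVERGVICAIIVGV
>CfGGPPS_typeIII_synthetic synthetic GGPPS stand-in (type III)
MLSMWKPWHQFHPLQWISSWYTPMSENGPQSYIQQQCEIPTCFVGFWCGFMSTSSMSYRRIEAAEWSEHR
CGYIMCSLLEDDVRGSDKMAQKSGFIANWPCVTWVLGHSNGVKPKIHGIVRWNKTQGALVWPFCQTHQTQ
YIKELNSKMEQKGMQWSECVFVCWRILCRMKCPIPVFLQWNMISHAPKYLKLIYHLAAGWRHMEINGWEM
NLNWEWLHTVNRHCGTGNLQHNAWNNHNGLDDTEDKIWYIMYHINVSNKGAYCWHIWHAARRNGLWMQPS
CNKCFGQWCEVNQSGAQKKMRTIYYASSCHFMYWHLPTRCAFSNPAHPNP
>AtGGPPS_typeII_synthetic synthetic GGPPS stand-in (type II)
MISEPVNGFCMNRTAYGGLTKAINFKFFEGYMIFNYIEFQIKKYRWPLNRTMSWFMFHKISTNCGVFALL
AWCTFASLVHDDLPSMDWHVRSWREVMGCALQTYEKPNVYYWTQNMMWYMLIRPFRMQMLEQTALSNNFF
NYHNSLQNMKFVWCYANQGWLRFHAQNYFETAFCGHGCMYAIVTEARAFAECNTKAMHHQVCVLLSEQFN
YREHRLGHMWPCWQWNRFSTRQIKMWTNIPDDNCDWHHHLPNKWWFLIHPQQPQPHLFTRRPLFYTCERI
GRGFWSRKPQNIYHMQTNYEHGHRVKAQAATEPTRAWKQHQCGNMATGNL
>PaGGPPS_typeII_synthetic synthetic GGPPS stand-in (type II)
MYMLIRWMHKAYHCKYTWVMQQVGFCFEPIHQSPFVITIWRWPWEVQCLSIRRNTPINWVMRKWALNKWA
SPICHTSIVEDDMLEADRIEYNQWMPHCWYAWNLIRFSHAMTTTCAMSWANTEMVLIWKCCCGNAEEYGI
FKKKRMQKGKAMPKSLEASTQQWVKVWATPNGNKCGNNERCWNTAISNWTCIIEPFLIVAIGHVFITHLH
MAELQVLPWNELIGEAPTTTERGRYKNTGEDDLCDVWANYQQEWPIFCEIKLIEATGTAAHPCPNITANN
LQLNPSTLGACSSGSVNMAAFMERVEKVESWTVTCVCYVASQVERNNMMS
>GaGGPPS_typeI_synthetic synthetic GGPPS stand-in (type I)
MLSQQYLPWINCYPVHLFWSCKNTLMGRWENKAKKSAEEKSNMIFQIMTCWRPSSTLEPVAHGACPQPCP
MCMIQYSILQDDVMDMKLPNACCHYNAFMYHHYSFGEQKTNTEGLLFFIYYSNCVEYLRFCKKSIGGGKY
QLTTKKCQCHNWRKIIWFYKRVKQSAGKNRRAVCHAHKCFITGIQWAMPMPTYFGKLHNYTPIHAGAYYI
HYGEALSNRQQCSHVRGEQHLRRELHKIKLDDLSDWEAYMIMSGGITNSLRSSHRAGMWFCWSGPNEGRQ
SYQCSGKSGLSEPTTLVQHHARSHPQMHIARNSHEMQLGEFPGSRPFHHI
>PhGGPPS_typeI_synthetic synthetic GGPPS stand-in (type I)
MSPSEHHENSPFSNLYNTETNWGFAERQNTQPNEIRQGEHPSILQMEANIGEWFMSRIQVLHVWRCRFTW
PSNFPFAKLEDDIQDMLFCFTNWRQEGPLWKYPTHYLWGIVLKNHRGQKLKSGHHWKWHHNVIAIIAQKY
EWCSQKNEQENFNATETGKEGQAGLECHHWPCEAPINPASPQHLLHEEVTCTNMIQIEVMCLMPRRMIQR
IRVEYRCGRYMYLFHCCARAWQPLYGSLTHDDNKDWPWCWWSPPRLQIMMYSMPAFLTMYYRVHCARVGY
TVEITMWGKWLYGGQFMSYEKAYAYSGWCTMTVIQSSYVMSITHTIFMSM
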