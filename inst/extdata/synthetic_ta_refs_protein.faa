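>hokW_syn|toxin|I|hok-sok
MAFCIPAKESEEHGPLRPLRDFLFRYFTTDIRNAPRLVMLVVTFCSAKFQRS
>relE_syn|toxin|II|relBE
MEILVGSLARGDDKDPADQLHKDKMLDYDGSTLIYPLPKGGLGGWYDANCIWPNDGSMIGGSNEVPESEEDRNCNGPLLNCYVRKDDGTLKWNLG
>relB_syn|antitoxin|II|relBE
MKPEGAFRMVSPQLESKKAAPEDCRTKIDLVKDKRGLMKSNGDQRKQGTDAKKPKLYYSDALVKRKDIFAGYPLSASFNDRDP
>vapC_syn|toxin|II|vapBC
MKNKVRLLRVVRSFLKRESTISGFGQGKPVVMPFGLHQLGDSILEASCVVANGDNLHASMLRRRMGVPGVNSAVKTIRATKGLLSHNTDLHVYDWADFTRVLEVTAGKAAQCLRLMINARAADYGKALED
>vapB_syn|antitoxin|II|vapBC
MSLYRNDVMEAERYRSLSRNPNGSSIVAPKKAKREPMDAGHDNSAELVARVGPDEVKDMETCDPTCVSALKRKEQNTQTG
>higB_syn|toxin|II|higBA
MAARWVFPPFGQAPLLYAKYFGGFVDLRAIQTVRFDSYCMEVEDEPMAYDGKGPVLFDLGYLVDLEYLVDDSVAVFVVGGKVKGANPAIQDW
>higA_syn|antitoxin|II|higBA
MPIGLLADCRYIIILEDVIYGDLGVPCVGDHLVFYGLARG
>mazF_syn|toxin|II|mazEF
MEGYILASFRHPATYLDAGPYLGTCFKCRLIIEVETKLHNFALGRLCFPPTLCLNVLPKSSIAWVNNGLLGALSCQLLFNEDHGKGNTKKVTYLHFLKVTDWYSKARKKGL
>mazE_syn|antitoxin|II|mazEF
MVKKNLPKGGQEFTAFDKHKEAISFSDPKHYRVICQAVCNTENEVNYATARLPGSAFTSVKIDAVWDKNALYRVFTATPFSD
>toxN_syn|toxin|III|toxIN
MALASNGSLWFLKRWEYVSNVDQLRQIPAVLELLIGQGLVELLDVLAFSVGVSESTILVEKSSTYGFLDASLIVGTACLKFLRLDANIGLLRSTYGPTECFAARAINDISFDVKLEPEDAPGFNAGPHDGLPNTKICPKELSIGAEDGECEASTASGNEIARSEPYQNPE
>cbtA_syn|toxin|IV|cbtA-cbeA
MPMEWLSIHHGTNDNEMIKLTFLDNCLLGFGEMGLTPVQVGSISSASAIANRVGAGVKELSTYSIVALGGVFASGAAFTVVPKELILRFRASNLDGGELVDFYRACIKAITHASIAIDMAHTPS
>cbeA_syn|antitoxin|IV|cbtA-cbeA
MNAELMGALPASLQLINVPDALELSIGNTRKEKEGAFIKDPIRSLNRVAKSRTQSSNAVSLYRLAPGHCVWKAVCPGTAEPERLVGNDEAVTMRISCPNSLLNWCSESEVIITCEKKLESAR
>ghoT_syn|toxin|V|ghoST
MQTESKQDKTRELRIGKPKLFKECATTEWIRDKTETSEYSGKLLEVWFEGIALALYL
>ghoS_syn|antitoxin|V|ghoST
MGQLPRFIRSQNTEQLCYAADKLLNSGLTVRIPAYLIKPSIPDPLSEFKMYQKLCATREIGEEILVFGCPLSSEYASEGKFSQTMGSSEDHMRSFVIP
>socB_syn|toxin|VI|socAB
MEIKLFYTDLIQTMRFSALMLQEINCTSGARVSAGVLNAYDAWIIWFEVVRITAKPGVLLIDCD
>socA_syn|antitoxin|VI|socAB
MFWRDEQDISVLAKYEYPCSISKTVTYLSPETKFDCISGTPDCILQYMERKDKIAEGDDSSREHKQLCTIGKEQFKTDDSMGRAQIPGYPIELISAGIDVWLKKSGVEANPLLKTAPDTS
>hha_syn|toxin|VII|hha-tomB
MSCGLAGRFKACPKAWIACVMLEVIVPHQQLPADLTRAKIGESTANVNHIKVGVNGIQVKMNAQRSGLNGVI
>tomB_syn|antitoxin|VII|hha-tomB
MPTGSYSNNSNNIINQYQLAKARKGPCKNGGGRGVSTNIGQVEGQLSLMTWAGIIAQPRFGNALSSRAHWATSLIPPFFYFKLPNETLQSRHSAKLYYEIRHTLLTELPIAPSKQKVADDLRIL
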