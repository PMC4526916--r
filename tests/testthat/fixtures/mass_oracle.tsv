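peptide	monoisotopic	average
YNARDGTQMSKFWKTDQPEWVTSYVYMRCQ	3717.680284	3720.131100
GQFWPAKCVIWGGAYNDVHSGVVSGENWK	3190.508316	3192.518300
GSTWMNISMVDQ	1367.584968	1368.534800
MITGQAM	750.340428	750.927200
SVRNVLFCGTMKTATHRMYAHLY	2698.329430	2700.168600
HQTWDL	798.366052	798.842600
VFPAEMI	805.404411	805.980800
EKLKCGVEERRGKKG	1715.946469	1717.003300
ANELVMSENNMNVCRCPVNVCDDF	2715.121942	2717.063300
TLYFWYNAD	1191.523673	1192.274800
NKGRVELWYEWLQPPWPLFPT	2655.363813	2657.029600
QIVHNHSCLWLMNTKCDSGMWAEVTFHF	3333.498029	3335.812900
WRPRCECGYWGKTDECIAC	2274.943114	2276.596200
YFLNTVLAQV	1166.633558	1167.353100
SHKGFWGNQAFKS	1492.721143	1493.623600
SCHQRH	766.329289	766.829000
LRYYFCATGVTTVLHQEPPKAPKYMCV	3114.549319	3116.675900
KLPLSGCGHVIQ	1250.680525	1251.497900
SMVAVLYGRCHIHQ	1612.796633	1613.904600
SVRAQRWNVRWSDWKYVHCNQKE	2974.452142	2976.292600
KNGTAQWWAPNDA	1457.668772	1458.533300
YLVVKRA	847.527972	848.044000
GLCLMEN	778.335344	778.937300
NIRPVNEDKP	1180.620035	1181.298900
RTQEHHHEWCLHPEIPVGWCYDEGLIVEW	3597.634660	3599.962800
FYFQLTQKPKKRRWRVEHHVKDLGS	3182.736622	3184.655600
AVGLP	455.274383	455.548300
IMHYRCLHCTEYDMQVKY	2332.026116	2333.730000
MRNMFHFKHAYWPYGMPWNI	2625.202047	2627.076100
SSITSEDHSWIMMNDWKDEVVQRHSMKR	3431.580908	3433.807300
HDDIVYLFRKGELQ	1731.894418	1732.932700
ICFKYGANLAIMTYPHAARVHQLWCWI	3204.597606	3206.806500
RVNDSRFDFMETNQNTLCPWGNNFRYSERQ	3723.669538	3725.993200
LNVTKTHYQPLMRS	1686.887557	1687.960100
TKYVVYDHGRTDWFWFDDHEPSRLCSKMPD	3729.676918	3732.077300
NMGIHSSPIFAWVY	1620.775881	1621.855300
KYSDWYFAQKYFYT	1908.872283	1910.085900
IFLSIHRCLHQCQ	1596.801720	1597.905300
GPGNYNYRHPTAGW	1588.717119	1589.667900
RGATIEVFQIPSQMRRGYNPTTVDMA	2937.458923	2939.328800
WRIQGATAMLYNWRYVMAHPEDSNMHCF	3426.530724	3428.899600
EKSNPFPSWNGRMDRRDRNVFKYE	3027.452202	3029.307300
CEAANVYKEIKCYNYM	1940.847071	1942.238900
EWVFLNNWGQYDTPSNIEFYCLV	2836.284299	2838.106900
NYEMFYGVNPFVP	1575.706799	1576.768200
CDWELE	793.295255	793.841100
VDIMQWASPDFHMDVIFP	2146.985617	2148.458300
YRQTAPQHHHADKQDITRWDQM	2761.289158	2762.971400
MLDYFNGYQQYKAPNYDFIDCP	2704.161405	2705.967500
RGKIQRMRDHEQACFWWD	2361.100754	2362.650500
YDIKSNYEAQEW	1544.678335	1545.603900
MTNLQNRYYLVTDFGIMEQEWSP	2834.304381	2836.157500
IQNSWGQDSQKRVNPSDQPDNHPATLINR	3314.614056	3316.512000
QMEREE	820.338516	820.868200
YARRWAFLMFNV	1572.802371	1573.860400
ILHCFKHNPPEYSCVRSGIFVLAPECYPCM	3452.600052	3455.081100
PGIEAWSGH	952.440278	953.009100
YKVCGMCSECHNYETEAVFQIRDAGD	2967.229576	2969.265300
NRCPF	635.284965	635.735500
IAEVWEMI	989.489203	990.173300
WPTQVLTIFFWPEFMEYGLMDCRE	3037.385276	3039.502200
REGKFLGFQWHTEAFLNDV	2293.127998	2294.521700
CCVHHSVESIDGCCAFPFKALELE	2636.153167	2638.026500
MPWGETSHLLVNPQMRYCTDICKAGLDP	3174.475896	3176.666700
VKCYNYM	919.393193	920.106500
AVSQLC	619.299945	619.731200
TYVFWGQIDHSAMFYSDDVFCDAATPSRAG	3356.454290	3358.624400
YCNTVKLCRDWYMHAVEWRG	2529.150405	2530.903000
HYWFHADPDNCNWKQIPQNMGTII	2927.327183	2929.249200
SISDGKHCS	932.402178	932.998000
QHQPT	609.287073	609.632100
QWKQHL	838.444971	838.952800
PRCLQMPGFMLGQPWAAGAHLYKLNAT	2970.481906	2972.510800
SAQHFQWGMHYSVPNITWTNGHIS	2797.281946	2799.041200
IYKWEIAKEVVVQGKRIGE	2244.263035	2245.618500
RHFQRRLLNQR	1522.870544	1523.747400
GANFANMARNCGCKEQSAGNDK	2284.973558	2286.485000
YEWTDSHTHVNKDESIPTLCQDYIV	2992.354898	2994.203700
PIWIQVMQQICGRLKGEKRCDHTD	2853.420038	2855.321800
QRGTVT	660.355486	660.720300
ISVHDLNGSAVLEWVLAFKITCMAFKDED	3250.604252	3252.712900
YGEPLCNA	865.364001	865.950000
SIKTKLRRCKWAQRHMGWIDSCGTA	2931.489453	2933.440400
SIAPQDMSKHMMQGDLLLHFVKIAQTAFL	3269.676310	3271.871800
DSFFFKQHLAGEIH	1674.815439	1675.839900
RVIHLEENMRSPYGIRGQDQAAKGDNQKWA	3466.727644	3468.814900
CWGDYVFRTYMYSKYLRAHD	2573.162015	2574.887500
AAHNAHINQTCNDMNGELHQCIFSP	2764.190429	2766.013200
QFLSMNGTPNSQGKTH	1745.815512	1746.898100
VVPIVMLYGQSRGTGWNDGC	2151.024124	2152.452000
HMEFAGIIAPCH	1324.605645	1325.558100
RYTAAHEWEETSTCCEYRENYKALWHMG	3463.480856	3465.763000
VGLAVGIFVIKPCEPAHLFLCCSYLAGMMM	3212.579103	3215.012300
LESKLCNKLTLIWMMKGCNHIL	2587.351079	2589.214100
MHAGQVMRKLQKGRWESNT	2256.136803	2257.597800
LMVAL	545.324704	545.735400
ADTDDKTLFPRGKMLRFRMYAVNHWSRI	3423.744483	3425.940700
CCMTR	612.218206	612.786700
GVKALLDVRQTDWWLEQTEYRCYRPTY	3388.666275	3390.779100
CNLCVSWPHFAAPMKTD	1918.852827	1920.238400
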