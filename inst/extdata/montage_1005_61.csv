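channel,x,y,z
Fp1,-0.32999086,0.94072624,-0.07835920
Fpz,0.00127232,0.99981084,-0.01940775
Fp2,0.33089891,0.94040166,-0.07842598
F7,-0.84762702,0.51239508,-0.13776688
F3,-0.59522030,0.62918936,0.49983351
Fz,0.00352573,0.66078569,0.75056635
F4,0.60662265,0.63551189,0.47763333
F8,0.84610803,0.51456684,-0.13900418
FC5,-0.92901942,0.22430888,0.29429313
FC1,-0.37535716,0.28663852,0.88144504
FC2,0.38602331,0.29339974,0.87458710
FC6,0.92958329,0.23300564,0.28562788
T7,-0.97657050,-0.18587435,-0.10844711
C3,-0.70687650,-0.12580193,0.69605998
Cz,0.00398259,-0.09106617,0.99583688
C4,0.72098774,-0.11709220,0.68298323
T8,0.97888357,-0.17281549,-0.10918684
CP5,-0.81833517,-0.47861568,0.31820524
CP1,-0.32642519,-0.43469219,0.83933861
CP2,0.35164547,-0.43125075,0.83088402
CP6,0.83148754,-0.46005555,0.31141190
P7,-0.70194958,-0.71181874,-0.02410113
P3,-0.48095979,-0.71487821,0.50756953
Pz,0.00280446,-0.70059652,0.71355214
P4,0.49850399,-0.70351885,0.50651258
P8,0.70683227,-0.70695418,-0.02457514
POz,0.00189082,-0.89610658,0.44383490
O1,-0.25232867,-0.96466600,0.07582711
O2,0.25639837,-0.96360961,0.07560687
AF7,-0.62007589,0.77535011,-0.11974179
AF3,-0.38939502,0.88781493,0.24526755
AF4,0.40439458,0.88014305,0.24862267
AF8,0.62032591,0.77515895,-0.11968443
F5,-0.78467891,0.58468656,0.20596272
F1,-0.31460619,0.65140408,0.69043151
F2,0.33560369,0.65498676,0.67702475
F6,0.79145606,0.58070357,0.19073716
FC3,-0.70811925,0.26728599,0.65354826
FCz,0.00405268,0.29514182,0.95544486
FC4,0.71748827,0.27323782,0.64074307
C5,-0.92795231,-0.15904745,0.33705849
C1,-0.37170760,-0.10263542,0.92265889
C2,0.39004357,-0.09964479,0.91538895
C6,0.93416196,-0.14301126,0.32693917
CP3,-0.61860560,-0.45754634,0.63873192
CP4,0.63764821,-0.44643933,0.62777120
P5,-0.63704798,-0.72244945,0.26876880
P1,-0.25107486,-0.70641391,0.66177095
P2,0.27592563,-0.69576010,0.66316132
P6,0.64264700,-0.71853474,0.26591852
PO5,-0.43003524,-0.88220080,0.19181097
PO3,-0.32164233,-0.88845024,0.32741775
PO4,0.32449649,-0.88971602,0.32110345
PO6,0.43959947,-0.87749505,0.19171526
FT7,-0.97610376,0.17063297,-0.13455791
FT8,0.97373028,0.18348334,-0.13484509
TP7,-0.87663947,-0.47559052,-0.07291705
TP8,0.88031953,-0.46867305,-0.07336957
PO7,-0.48997942,-0.87137701,0.02494552
PO8,0.49519324,-0.86844337,0.02428525
Oz,0.00092900,-0.99196026,0.12654634
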