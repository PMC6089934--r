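"mode","corr_len_um","bvtv_pct","tbth_um","tbs_um"
"voi3d",50,40,84.8022739629641,113.220874905601
"voi3d",50,44,89.698375395957,106.826426474341
"voi3d",50,48,94.8079075591139,100.635205178993
"voi3d",50,52,100.392771999425,94.9119866483933
"voi3d",50,56,106.607975497765,89.6316745724664
"voi3d",50,60,113.233326511712,84.770706334151
"voi3d",60,40,104.967559707582,138.328398378036
"voi3d",60,44,110.94409992225,129.961150961994
"voi3d",60,48,116.865223508272,123.454081874572
"voi3d",60,52,122.861141838416,117.140438370387
"voi3d",60,56,129.842817903752,111.268135445851
"voi3d",60,60,137.444345907354,105.687777474657
"voi3d",75,40,134.529020135336,174.280208958736
"voi3d",75,44,141.821442524388,165.109523322671
"voi3d",75,48,149.371413462577,156.808843514767
"voi3d",75,52,156.966787986511,148.992134942984
"voi3d",75,56,165.261571198988,141.981216712549
"voi3d",75,60,173.969480489902,134.866223217648
"voi3d",100,40,183.148222983831,234.643192534996
"voi3d",100,44,192.289872014696,222.920193213053
"voi3d",100,48,202.676962235836,212.624534806815
"voi3d",100,52,212.591725166407,201.633390388931
"voi3d",100,56,223.356500590264,191.44615116272
"voi3d",100,60,234.655985590315,182.462178623685
"voi3d",125,40,234.549403366743,296.53043026553
"voi3d",125,44,245.544837064456,282.120138566606
"voi3d",125,48,257.663306169381,268.02258193255
"voi3d",125,52,271.0088819061,254.715059615349
"voi3d",125,56,283.563237306789,243.104020654308
"voi3d",125,60,299.033272082632,231.702242519271
"voi3d",150,40,284.541409081904,356.138718752434
"voi3d",150,44,303.662170792866,340.976298922293
"voi3d",150,48,315.985573270735,326.991522016354
"voi3d",150,52,329.95966357428,312.348730887767
"voi3d",150,56,345.532609523349,300.382970153915
"voi3d",150,60,363.192017337838,286.185826079606
"voi3d",175,40,336.333162825632,412.852502222116
"voi3d",175,44,349.903420123961,392.384021363609
"voi3d",175,48,365.865628167533,377.933892380518
"voi3d",175,52,384.242557338671,363.713845485365
"voi3d",175,56,405.713871145768,351.127382180211
"voi3d",175,60,426.727619054107,336.619194892584
"voi3d",200,40,387.833047581081,477.065382818052
"voi3d",200,44,407.405984164386,452.239401250124
"voi3d",200,48,425.260889916352,431.640885445158
"voi3d",200,52,443.219881477107,416.222609886236
"voi3d",200,56,465.095486892265,400.22002415499
"voi3d",200,60,495.301294411054,382.13381172178
"voi3d",250,40,513.794126312613,588.904294076966
"voi3d",250,44,534.154850707968,562.881674308033
"voi3d",250,48,554.002615300071,534.41626679308
"voi3d",250,52,580.766531745617,510.989901482543
"voi3d",250,56,602.299376492209,489.462030792689
"voi3d",250,60,628.640599063135,468.91662298022
"voi3d",300,40,626.690465476968,689.260198350981
"voi3d",300,44,651.607360313429,656.138420599417
"voi3d",300,48,677.810158939202,623.368474047018
"voi3d",300,52,704.698270782206,594.816429276977
"voi3d",300,56,737.07848493249,567.812536375047
"voi3d",300,60,767.906599947573,540.852178862046
"slice2d",50,40,102.612095124709,143.929962941744
"slice2d",50,44,110.252934213552,133.260373722604
"slice2d",50,48,117.845988682872,124.011153139695
"slice2d",50,52,125.941283999626,116.05891392105
"slice2d",50,56,136.019019470664,109.088685166392
"slice2d",50,60,145.656014125737,101.595635328267
"slice2d",60,40,126.251500711078,174.076554562697
"slice2d",60,44,134.564110009224,162.181655076201
"slice2d",60,48,142.686049321873,151.36516860555
"slice2d",60,52,152.150177203905,141.406058276283
"slice2d",60,56,163.378721840331,133.344544148606
"slice2d",60,60,175.965090382071,124.18393715788
"slice2d",75,40,162.344374292121,220.945198904073
"slice2d",75,44,173.020312564435,206.676043196106
"slice2d",75,48,183.800207404387,190.518965068538
"slice2d",75,52,195.279858946419,177.529847766727
"slice2d",75,56,208.997280366073,166.428364648782
"slice2d",75,60,221.679254908643,156.445312885861
"slice2d",100,40,222.510797115464,301.874255598829
"slice2d",100,44,237.36260982806,279.459082917915
"slice2d",100,48,252.038014505347,259.550404134344
"slice2d",100,52,264.392589342551,242.792265316577
"slice2d",100,56,279.690312438278,227.577415704786
"slice2d",100,60,296.557788102388,213.292251496711
"slice2d",125,40,274.790976193415,377.264563278634
"slice2d",125,44,292.446826918113,355.092547152417
"slice2d",125,48,307.813186385465,333.956426875417
"slice2d",125,52,328.148698221464,314.791286667239
"slice2d",125,56,348.787736743691,298.752956674333
"slice2d",125,60,369.792834574837,279.241339017126
"slice2d",150,40,330.544347101862,447.887676719841
"slice2d",150,44,349.043361181666,424.680512221166
"slice2d",150,48,365.558208724779,402.3554345753
"slice2d",150,52,386.792944137552,379.059062904683
"slice2d",150,56,408.995156427421,359.779528588625
"slice2d",150,60,436.212674997086,337.895535714019
"slice2d",175,40,382.171184826972,520.991289166893
"slice2d",175,44,401.741476650325,491.664187044452
"slice2d",175,48,428.205685135459,469.614315314535
"slice2d",175,52,449.181249858611,444.047580735907
"slice2d",175,56,476.627719011065,417.55256143714
"slice2d",175,60,511.243739657332,395.387094556959
"slice2d",200,40,439.529128901991,587.357554838576
"slice2d",200,44,460.4488545704,559.048489262525
"slice2d",200,48,481.561929436188,527.198588248514
"slice2d",200,52,510.00762421148,499.483468945857
"slice2d",200,56,563.052007441347,478.881565513694
"slice2d",200,60,604.638809087685,455.546267490879
"slice2d",250,40,574.952442949671,744.252437750819
"slice2d",250,44,607.892856956865,703.953501660052
"slice2d",250,48,638.422874439151,666.07987663252
"slice2d",250,52,671.446631084658,618.860660417485
"slice2d",250,56,738.078242839576,591.048960489389
"slice2d",250,60,793.901926394214,560.878355747113
"slice2d",300,40,697.289477425432,938.702934487285
"slice2d",300,44,735.396522594215,874.043483870267
"slice2d",300,48,797.844887971622,815.347155471334
"slice2d",300,52,863.46082017435,756.543564200337
"slice2d",300,56,956.614786222026,713.708484803978
"slice2d",300,60,1030.22091178138,675.91681709324
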