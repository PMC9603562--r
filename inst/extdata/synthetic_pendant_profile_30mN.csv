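x_m,z_m
0,0
2.41594464652601e-05,2.43613194120293e-07
4.83090859233596e-05,9.73513622213958e-07
7.24391370734932e-05,2.18930073518352e-06
9.65398377658032e-05,3.89030806836107e-06
0.000120601454514828,6.0756042052284e-06
0.000144614291957465,8.74399414185291e-06
0.000168568702237258,1.18940210354999e-05
0.000192455094297072,1.55239683323632e-05
0.000216263943062545,1.96318622688279e-05
0.000239985798499059,2.42154747397993e-05
0.000263611294525406,2.92723265267312e-05
0.000287131157767793,3.47996908771019e-05
0.000310536216138377,4.07945974262386e-05
0.00033381740722307,4.7253836451575e-05
0.00035696578646402,5.41739634486505e-05
0.000379972535122799,6.15513040174312e-05
0.000402828968011079,6.93819590468445e-05
0.000425526540976277,7.7661810184782e-05
0.000448056858130479,8.63865255802392e-05
0.000470411678811713,9.55515658837207e-05
0.000492582924267508,0.000105152190491563
0.000514562684051505,0.00011518346401939
0.000536343222124783,0.000125640262989561
0.000557916982654431,0.000136517282717118
0.000579276595502793,0.000147809044378535
0.000600414881401734,0.000159509902247309
0.000621324856807162,0.000171614051080314
0.000641999738429948,0.000184115533638757
0.000662432947440293,0.000197008248327497
0.000682618113343479,0.00021028595693655
0.000702549077525804,0.00022394229246862
0.000722219896470392,0.000237970767036668
0.000741624844643398,0.000252364779815637
0.000760758417051942,0.000267117625032723
0.000779615331475941,0.000282222499980789
0.000798190530376739,0.000297672513039855
0.000816479182486224,0.000313460691691918
0.000834476315745674,0.000329580394381504
0.000852177790340101,0.000346024218858099
0.000869579580546978,0.000362784861933553
0.000886677770974306,0.000379855106824794
0.000903468675828219,0.000397227695387036
0.000919948838697463,0.000414895335801684
0.000936115032062218,0.000432850710166621
0.000951964256535663,0.000451086481977984
0.000967493739847115,0.000469595303493132
0.000982700935575946,0.000488369822965076
0.000997583521645834,0.000507402691739253
0.00101213939858919,0.00052668657120415
0.0010263666875919,0.000546214139587856
0.00104026372832865,0.000565978098593282
0.00105382907659946,0.000585971179865365
0.001067061501778,0.00060618615128421
0.00107995998408255,0.000626615823078701
0.00109252371168041,0.000647253053755744
0.0011047520776367,0.000668090755840858
0.00111664467671847,0.000689121901426446
0.00112820130206499,0.000710339527524605
0.00113942194173515,0.000731736741221915
0.0011503067751426,0.000753306724634164
0.0011608561693895,0.000775042739659493
0.00117107067550926,0.000796938132528941
0.00118095102462875,0.000818986338153844
0.00119049812406017,0.00084118088427002
0.00119971305333263,0.00086351539537908
0.00120859706017327,0.00088598359648766
0.00121715155644746,0.000908579316645726
0.00122537811406752,0.000931296492285502
0.00123327846087894,0.000954129170362902
0.00124085447653304,0.000977071511303687
0.00124810818835455,0.00100011779175685
0.00125504176721239,0.00102326240715804
0.00126165752340168,0.00104649987410603
0.00126795790254449,0.00106982483255558
0.00127394522288019,0.00109323211217243
0.00127962219933997,0.00111671659221231
0.00128499191681304,0.00114027322715581
0.00129005732242807,0.00116389716940902
0.00129482147864938,0.00118758370307867
0.00129928755943511,0.00121132824514056
0.0013034588464593,0.00123512634645181
0.00130733872540306,0.00125897369261133
0.00131093068231972,0.0012828661046727
0.00131423830007849,0.00130679953971396
0.00131726525489103,0.00133077009126854
0.00132001531292476,0.00135477398962177
0.0013224923270067,0.00137880760197714
0.00132470023342124,0.00140286743249667
0.00132664304880499,0.00142695012221942
0.00132832486714148,0.00145105244886226
0.00132974985685846,0.00147517132650689
0.00133092225803006,0.00149930380517692
0.00133184637968576,0.00152344707030872
0.00133252659722831,0.00154759844211956
0.00133296734996186,0.00157175537487655
0.00133317313873185,0.00159591545606952
0.00133314852367772,0.00162007640549089
0.00133289812209923,0.00164423607422542
0.00133242660643723,0.00166839244355246
0.00133173870236909,0.00169254362376317
0.00133083918701911,0.00171668785289479
0.00132973288728386,0.00174082349538414
0.00132842467827223,0.00176494904064186
0.00132691948185965,0.00178906310154898
0.00132522226535583,0.00181316441287703
0.00132333804028512,0.00183725182963266
0.00132127186127829,0.00186132432532731
0.00131902882507431,0.00188538099017257
0.00131661406963066,0.00190942102920107
0.00131403277334,0.00193344376031306
0.00131129015435143,0.00195744861224785
0.00130839140695678,0.00198143511465898
0.00130534171463962,0.00200540289572961
0.001302146605021,0.00202935172699652
0.00129881145066978,0.00205328145922688
0.0012953416619876,0.00207719204270801
0.00129174268709609,0.00210108352474267
0.00128802001180509,0.00212495604705825
0.00128417915965729,0.00214880984312688
0.00128022569204406,0.00217264523539356
0.00127616520838698,0.00219646263240915
0.00127200334637914,0.0022202625258646
0.00126774578227954,0.00224404548752291
0.00126339823125393,0.0022678121660449
0.00125896644775422,0.00229156328370474
0.00125445622592872,0.00231529963299118
0.00124987340005437,0.00233902207309019
0.00124522384498172,0.00236273152624479
0.00124051347658284,0.00238642897398764
0.00123574825219153,0.00241011545324232
0.00123093417102455,0.00243379205228899
0.00122607727457202,0.00245745990659046
0.00122118364694419,0.00248112019447501
0.00121625941516125,0.00250477413267222
0.00121131074937194,0.00252842297169905
0.00120634386298612,0.00255206799109322
0.00120136501270563,0.00257571049449204
0.00119638049843697,0.00259935180455524
0.00119139666306892,0.00262299325773109
0.0011864198920971,0.00264663619886618
0.00118145661307731,0.00267028197566006
0.00117651329488857,0.0026939319329672
0.00117159644678653,0.00271758740694992
0.00116671261722733,0.00274124971908731
0.00116186839244193,0.00276492017004684
0.0011570703947405,0.00278860003342679
0.00115232528052677,0.0028122905493797
0.00114763973800204,0.00283599291812866
0.00114302048453929,0.00285970829339068
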