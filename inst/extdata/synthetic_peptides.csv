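peptide_id,sequence,modifications,accession,unique,score,control_D1,control_D2,control_D3,strain_0h_D1,strain_0h_D2,strain_0h_D3,strain_24h_D1,strain_24h_D2,strain_24h_D3
pep000001,CFINPVAGRKRSYGMI,,P00001,TRUE,12.51447133629295,463713.10887420306,348353.80631481425,328552.41732282157,166797.23475827114,136593.54400737205,NA,854460.3694180645,800220.6072738261,801532.8727343772
pep000002,HSTVTCESFW,8:phospho,P00001,TRUE,14.229580133189089,760777.6450615127,718257.0725496756,855431.2822983727,NA,195285.33856714246,296882.43011537637,1172516.9677695064,950795.5340219685,1831505.2886303612
pep000003,YQDISNQDQHD,,P00001,TRUE,9.569062166162496,NA,102701.62316749131,135485.06308901648,41504.97999898364,42913.52289253647,67571.6891298077,NA,204373.41131697912,281180.77110153605
pep000004,RFIWLVLN,,P00001,TRUE,15.258221672098138,814482.9152229887,NA,NA,338655.80250349187,NA,274284.41476690775,2142012.8875490455,NA,1504341.4825714903
pep000005,CLNYQTQDIQWTTMHRGQ,12:phospho,P00002,FALSE,27.961828795135233,118041727.19567737,140427770.76793373,170025077.71301237,102408074.7148532,158495221.0931849,168197571.486813,127491285.28955577,129207901.69737397,148407213.70801076
pep000006,HLFGSMENQWHKHC,,P00002,TRUE,20.367603245986334,29901724.003223244,41887251.835190356,39160118.55714557,25923357.107021276,30141734.40141357,32124544.785960205,31446430.57446809,32682208.67042629,37819191.83813152
pep000007,SPWYRHEAIYSM,,P00002,TRUE,23.36116380000005,79854205.06969742,87483028.01674335,111978439.12868196,94579296.83990479,94062683.41561237,113911616.19399731,92487587.23133184,107936823.34939927,125776093.61130543
pep000008,SYIDEYNTLYMIQTCMPQG,14:phospho,P00002,TRUE,19.60543093937186,NA,6963936.367732476,7506181.624274376,6575059.465380177,5166336.960705344,6971965.918195747,NA,5690850.949969044,8356176.771584853
pep000009,INEPSSAIILIVKHHLM,5:phospho,P00002,TRUE,19.40008126360741,21721622.266259052,21628656.638982363,27066211.827652816,21903094.643074393,22186505.24144333,23612170.2194427,21871147.577855557,19675984.566264167,NA
pep000010,AWLPMMYHYKKFQQGALTTH,,P00003,TRUE,11.89562901135849,264807.0206978541,NA,273846.74768795836,245060.77852055873,250756.32948086446,225939.63897406962,202502.832551727,NA,270136.2643520797
pep000011,KYGVTFYDQACELA,,P00003,TRUE,5.253408366271943,163394.2985911576,239765.64374261914,188508.48468255968,170184.3060606079,175813.53964451843,220022.0688287388,147834.0166272848,263564.92339998914,223406.6965665016
pep000012,FIPVLGHKSTPIHYVT,,P00003,TRUE,3.2994776804881734,24094.82026794255,31921.396388164798,23597.001415621115,18947.546597656412,28907.652498104904,22622.715356826186,NA,24284.004619128795,NA
pep000013,ACTCPTDVCFNPLGLL,,P00003,TRUE,3.511136848448811,NA,31364.69808769929,41530.107697716834,29165.66859839293,31375.183726259987,40990.050726300295,NA,28206.462047751655,45210.043055891736
pep000014,GSSDEDDSCRYKHKECN,11:phospho,P00004,TRUE,8.453205562866188,194662.6892785591,182405.561390733,160381.14071430586,194885.01891822167,252900.5374809174,161976.69705504944,179933.09775736477,221670.34647515943,136970.59938706725
pep000015,KMHPFMAWNCTNDV,,P00004,TRUE,11.137424232480049,493819.15567404096,583865.778063352,384736.40443662496,555902.9613765446,597944.3614037362,398644.63662492647,561453.6467005195,NA,NA
pep000016,RDWVTGLILPYGYYKSIH,,P00004,TRUE,13.20073630365318,313738.20470635156,319074.74722164223,279050.7574552018,357579.7383011548,315522.0487477273,310369.6777955909,273949.79734958714,257890.41027951034,308460.4970426404
pep000017,LTVIWLMTNCWPPWLSFEV,,P00004,TRUE,16.69466313892749,612300.7810306352,813689.6161013525,728135.4890886601,534272.6148015317,856295.2149852824,530536.2740441189,796992.7872421099,607514.6181435635,NA
pep000018,ASTNCVNRWGSR,,P00004,TRUE,9.131590073543913,235359.69070738365,225719.1763451406,200745.35702086287,259872.5733246802,NA,138038.21305732988,229951.66590367866,211175.95119960906,207220.46709670537
pep000019,WDQAASMENPLLHV,,P00005,TRUE,13.894467035259218,3834132.1676517925,2646409.588684411,2581777.236687056,3408813.2662951634,2350968.9603020847,3033623.946802471,3509895.528265985,2870862.1977653513,3206008.7131820507
pep000020,TYKMNIVFVSLK,10:phospho,P00005,TRUE,15.00851438198438,5457401.330999031,4845500.633520096,5734170.025666009,NA,5325528.484345205,6694060.927471082,3980923.0536881303,5752739.361571512,7214386.034592123
pep000021,MGNWEDQIGELSSYLGWE,,P00005,TRUE,18.309008613202387,12349322.809829624,8889807.09795298,NA,12814075.54012739,11657161.744959028,8702928.403862493,11012877.21074395,9528864.768780246,11892001.255319016
pep000022,KERYTHRFQRRSW,,P00005,TRUE,16.55565315194519,3760293.2864244613,3491411.9880460734,4123667.576924097,5435554.938906525,2474540.0821597567,4097501.5510675157,3533959.5942846276,2697486.8897979045,NA
pep000023,IFHYSSKMMWLCGYQQ,,P00005,TRUE,16.166838361899416,NA,1175448.7357790242,1322973.4853478118,1152331.465121834,NA,949516.965313343,1050745.752380147,1099778.2892385498,815998.7061369336
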