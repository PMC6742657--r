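cell_id,donor,group,nuclear_area,cytoplasmic_area
control_c1,D1,control,153.67292834997446,1347.284240891641
control_c2,D2,control,162.52002636399885,1397.4628426071724
control_c3,D3,control,274.1259634372101,2272.7154263332845
control_c4,D1,control,164.42902546526648,1737.183967562403
control_c5,D2,control,127.63555407650067,1698.2028358440828
control_c6,D3,control,180.79559375762494,2529.9375228567806
control_c7,D1,control,140.52437963924964,2292.9728457973406
control_c8,D2,control,196.4709508840938,1545.4210335275159
control_c9,D3,control,216.74912770570043,1445.1734663030818
control_c10,D1,control,162.724197702295,1913.3923426690928
control_c11,D2,control,161.99690485007204,1488.0856223476235
control_c12,D3,control,184.94707026020293,1913.922930386731
control_c13,D1,control,206.90438523361468,1919.9795452997387
control_c14,D2,control,173.23833232138213,1601.6561732634436
control_c15,D3,control,144.83581955091196,1745.1553439508607
control_c16,D1,control,171.42469007474102,1658.6666481490522
control_c17,D2,control,146.41848661497653,1642.6611264240037
control_c18,D3,control,169.24542129286422,2158.4204724575916
control_c19,D1,control,146.1796221785445,1718.3431859271068
control_c20,D2,control,133.03394928301475,1577.9950963646897
control_c21,D3,control,179.48333836830912,2410.995616559855
control_c22,D1,control,136.22354877118653,1547.1107310929801
control_c23,D2,control,118.64261011230714,1782.254323941665
control_c24,D3,control,235.4661198236386,2607.6398794938546
control_c25,D1,control,155.895492806905,1733.2664722996092
control_c26,D2,control,130.47390874922394,1590.273420493578
control_c27,D3,control,253.06823999517022,2631.228966203079
control_c28,D1,control,163.45029646762188,1909.3400443077587
control_c29,D2,control,150.99781770680264,1850.4253942441655
control_c30,D3,control,237.81737884077035,2247.3390938688162
strain_c1,D1,strain,217.6136887206991,1774.8801140274159
strain_c2,D2,strain,225.58808033085316,2622.4601354162987
strain_c3,D3,strain,282.49646100561364,2392.4188569990943
strain_c4,D1,strain,205.724747458007,2890.925332357128
strain_c5,D2,strain,193.564937081357,2701.7803421478575
strain_c6,D3,strain,237.77253253993942,2548.4318990491347
strain_c7,D1,strain,174.97128636695408,1656.447953227316
strain_c8,D2,strain,173.46190096475723,1831.6655351093182
strain_c9,D3,strain,241.84679367689526,2775.5156312272215
strain_c10,D1,strain,150.09613737371424,1896.0869563090098
strain_c11,D2,strain,284.9155892314103,1950.5379666444865
strain_c12,D3,strain,309.0977666542297,2251.1001597238715
strain_c13,D1,strain,153.8429990953022,1963.5184680975701
strain_c14,D2,strain,182.4592587383729,1808.171616469855
strain_c15,D3,strain,231.2428714586388,1988.3192336265593
strain_c16,D1,strain,213.94311001848894,1852.7156389242368
strain_c17,D2,strain,192.8465455539437,2429.2431190951756
strain_c18,D3,strain,261.9701363576246,2402.7693238186607
strain_c19,D1,strain,185.97378208046618,2198.7585371193345
strain_c20,D2,strain,194.20467837768783,1565.134947408345
strain_c21,D3,strain,317.82294915779585,2629.2373768782936
strain_c22,D1,strain,179.72526016234414,2165.274450864477
strain_c23,D2,strain,254.4554728105045,2182.597451512788
strain_c24,D3,strain,191.7045434389542,2703.7353430928106
strain_c25,D1,strain,206.8219598934448,1770.9476875795563
strain_c26,D2,strain,199.89732009950163,1787.9812947399398
strain_c27,D3,strain,260.27885690877264,2222.9919024975243
strain_c28,D1,strain,199.60471627756817,2019.6562276324519
strain_c29,D2,strain,179.34216346207768,1757.9439548880086
strain_c30,D3,strain,236.6526184216823,2438.3336143605475
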