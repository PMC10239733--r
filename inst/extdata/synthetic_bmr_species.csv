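"order","family","genus","species","habitat","body_mass_kg","trait","value","is_juvenile","is_sedated"
"AQ_order_01","AQ_family_01","AQ_genus_01","AQ_species_001","aquatic",121.533,"BMR",5238.46,FALSE,FALSE
"AQ_order_01","AQ_family_01","AQ_genus_02","AQ_species_002","aquatic",90.5466,"BMR",3035.43,FALSE,FALSE
"AQ_order_01","AQ_family_02","AQ_genus_03","AQ_species_003","aquatic",456.187,"BMR",15355.1,FALSE,FALSE
"AQ_order_02","AQ_family_03","AQ_genus_04","AQ_species_004","aquatic",162.666,"BMR",1561.95,FALSE,FALSE
"AQ_order_02","AQ_family_04","AQ_genus_05","AQ_species_005","aquatic",11.7875,"BMR",279.763,FALSE,FALSE
"AQ_order_02","AQ_family_04","AQ_genus_06","AQ_species_006","aquatic",51.2716,"BMR",816.921,FALSE,FALSE
"AQ_order_02","AQ_family_05","AQ_genus_07","AQ_species_007","aquatic",31.2706,"BMR",760.718,FALSE,FALSE
"AQ_order_02","AQ_family_05","AQ_genus_08","AQ_species_008","aquatic",49.2192,"BMR",1025.66,FALSE,FALSE
"AQ_order_02","AQ_family_06","AQ_genus_09","AQ_species_009","aquatic",205.292,"BMR",3188.62,FALSE,FALSE
"AQ_order_03","AQ_family_07","AQ_genus_10","AQ_species_010","aquatic",2058.04,"BMR",35614.9,FALSE,FALSE
"AQ_order_03","AQ_family_07","AQ_genus_11","AQ_species_011","aquatic",23.7602,"BMR",2241.47,FALSE,FALSE
"AQ_order_03","AQ_family_07","AQ_genus_12","AQ_species_012","aquatic",38.9609,"BMR",2545.93,FALSE,FALSE
"AQ_order_03","AQ_family_07","AQ_genus_12","AQ_species_013","aquatic",248.613,"BMR",6625.71,FALSE,FALSE
"AQ_order_03","AQ_family_07","AQ_genus_13","AQ_species_014","aquatic",425.915,"BMR",14748.4,FALSE,FALSE
"AQ_order_04","AQ_family_08","AQ_genus_14","AQ_species_015","aquatic",33.3608,"BMR",918.492,FALSE,FALSE
"AQ_order_04","AQ_family_09","AQ_genus_15","AQ_species_016","aquatic",15.4941,"BMR",725.788,FALSE,FALSE
"AQ_order_04","AQ_family_10","AQ_genus_16","AQ_species_017","aquatic",1157.87,"BMR",14848.1,FALSE,FALSE
"AQ_order_04","AQ_family_10","AQ_genus_16","AQ_species_018","aquatic",22.2489,"BMR",1134.24,FALSE,FALSE
"AQ_order_04","AQ_family_10","AQ_genus_17","AQ_species_019","aquatic",631.297,"BMR",11759.5,FALSE,FALSE
"AQ_order_04","AQ_family_10","AQ_genus_18","AQ_species_020","aquatic",361.053,"BMR",7144.94,FALSE,FALSE
"TE_order_01","TE_family_01","TE_genus_01","TE_species_001","terrestrial",1046.18,"BMR",11136.3,FALSE,FALSE
"TE_order_01","TE_family_02","TE_genus_02","TE_species_002","terrestrial",82.1192,"BMR",940.713,FALSE,FALSE
"TE_order_02","TE_family_03","TE_genus_03","TE_species_003","terrestrial",17.4413,"BMR",517.583,FALSE,FALSE
"TE_order_02","TE_family_04","TE_genus_04","TE_species_004","terrestrial",3707.87,"BMR",25109.5,FALSE,FALSE
"TE_order_02","TE_family_05","TE_genus_05","TE_species_005","terrestrial",13.99,"BMR",307.703,FALSE,FALSE
"TE_order_02","TE_family_05","TE_genus_06","TE_species_006","terrestrial",36.7793,"BMR",600.086,FALSE,FALSE
"TE_order_03","TE_family_06","TE_genus_07","TE_species_007","terrestrial",10.2766,"BMR",132.536,FALSE,FALSE
"TE_order_03","TE_family_07","TE_genus_08","TE_species_008","terrestrial",83.0328,"BMR",1195.28,FALSE,FALSE
"TE_order_03","TE_family_07","TE_genus_09","TE_species_009","terrestrial",692.591,"BMR",4566.3,FALSE,FALSE
"TE_order_03","TE_family_07","TE_genus_10","TE_species_010","terrestrial",48.2317,"BMR",847.958,FALSE,FALSE
"TE_order_03","TE_family_08","TE_genus_11","TE_species_011","terrestrial",2282.56,"BMR",25154.3,FALSE,FALSE
"TE_order_03","TE_family_08","TE_genus_12","TE_species_012","terrestrial",457.283,"BMR",5558.05,FALSE,FALSE
"TE_order_03","TE_family_08","TE_genus_13","TE_species_013","terrestrial",89.0437,"BMR",2099.16,FALSE,FALSE
"TE_order_04","TE_family_09","TE_genus_14","TE_species_014","terrestrial",289.108,"BMR",3861.76,FALSE,FALSE
"TE_order_04","TE_family_10","TE_genus_15","TE_species_015","terrestrial",137.512,"BMR",2005,FALSE,FALSE
"TE_order_05","TE_family_11","TE_genus_16","TE_species_016","terrestrial",1998.6,"BMR",14397.4,FALSE,FALSE
"TE_order_05","TE_family_11","TE_genus_16","TE_species_017","terrestrial",103.077,"BMR",1898.62,FALSE,FALSE
"TE_order_05","TE_family_12","TE_genus_17","TE_species_018","terrestrial",27.1519,"BMR",425.998,FALSE,FALSE
"TE_order_05","TE_family_12","TE_genus_17","TE_species_019","terrestrial",14.7012,"BMR",181.038,FALSE,FALSE
"TE_order_05","TE_family_13","TE_genus_18","TE_species_020","terrestrial",31.0166,"BMR",719.552,FALSE,FALSE
"TE_order_05","TE_family_14","TE_genus_19","TE_species_021","terrestrial",239.509,"BMR",2669.27,FALSE,FALSE
"TE_order_06","TE_family_15","TE_genus_20","TE_species_022","terrestrial",26.2333,"BMR",514.695,FALSE,FALSE
"TE_order_06","TE_family_16","TE_genus_21","TE_species_023","terrestrial",161.878,"BMR",1715.21,FALSE,FALSE
"TE_order_06","TE_family_17","TE_genus_22","TE_species_024","terrestrial",31.8148,"BMR",413.309,FALSE,FALSE
"TE_order_06","TE_family_17","TE_genus_23","TE_species_025","terrestrial",182.608,"BMR",2433.9,FALSE,FALSE
"TE_order_06","TE_family_17","TE_genus_23","TE_species_026","terrestrial",16.0379,"BMR",200.821,FALSE,FALSE
"TE_order_06","TE_family_17","TE_genus_24","TE_species_027","terrestrial",440.736,"BMR",3992.71,FALSE,FALSE
"TE_order_07","TE_family_18","TE_genus_25","TE_species_028","terrestrial",36.7266,"BMR",702.351,FALSE,FALSE
"TE_order_07","TE_family_18","TE_genus_26","TE_species_029","terrestrial",2461.98,"BMR",20173.1,FALSE,FALSE
"TE_order_07","TE_family_18","TE_genus_26","TE_species_030","terrestrial",21.3196,"BMR",463.401,FALSE,FALSE
"TE_order_07","TE_family_18","TE_genus_27","TE_species_031","terrestrial",1347.6,"BMR",11855.7,FALSE,FALSE
"TE_order_07","TE_family_18","TE_genus_28","TE_species_032","terrestrial",249.841,"BMR",4278.1,FALSE,FALSE
"TE_order_07","TE_family_18","TE_genus_29","TE_species_033","terrestrial",225.339,"BMR",2960.99,FALSE,FALSE
"TE_order_07","TE_family_18","TE_genus_30","TE_species_034","terrestrial",495.829,"BMR",5272.7,FALSE,FALSE
"TE_order_07","TE_family_18","TE_genus_31","TE_species_035","terrestrial",1905.56,"BMR",17620.6,FALSE,FALSE
"TE_order_07","TE_family_18","TE_genus_32","TE_species_036","terrestrial",30.9175,"BMR",581.342,FALSE,FALSE
"TE_order_08","TE_family_19","TE_genus_33","TE_species_037","terrestrial",1911.74,"BMR",12168.9,FALSE,FALSE
"TE_order_08","TE_family_19","TE_genus_33","TE_species_038","terrestrial",19.4989,"BMR",368.107,FALSE,FALSE
"TE_order_08","TE_family_20","TE_genus_34","TE_species_039","terrestrial",668.639,"BMR",5734.74,FALSE,FALSE
"TE_order_08","TE_family_20","TE_genus_34","TE_species_040","terrestrial",189.805,"BMR",3002.1,FALSE,FALSE
"TE_order_09","TE_family_21","TE_genus_35","TE_species_041","terrestrial",20.8215,"BMR",317.95,FALSE,FALSE
"TE_order_09","TE_family_21","TE_genus_36","TE_species_042","terrestrial",239.288,"BMR",3503.4,FALSE,FALSE
"TE_order_09","TE_family_22","TE_genus_37","TE_species_043","terrestrial",56.7121,"BMR",621.37,FALSE,FALSE
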