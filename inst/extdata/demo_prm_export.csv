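peptide_sequence,sample_id,replicate_id,fragment_id,light_area,heavy_area,points_across_peak,mass_error_ppm,truncated
SSEDPNEDIVER,P001_B,rep1,y4,170020.550649543,164652.456822026,10,0,FALSE
SSEDPNEDIVER,P001_B,rep1,y5,143657.79018415,130337.029536317,10,0,FALSE
SSEDPNEDIVER,P001_B,rep1,y6,75816.4619967762,70825.8928914538,10,0,FALSE
SSEDPNEDIVER,P001_B,rep2,y4,135467.598338547,123632.476993044,10,0,FALSE
SSEDPNEDIVER,P001_B,rep2,y5,66498.6553830141,58961.7790914073,10,0,FALSE
SSEDPNEDIVER,P001_B,rep2,y6,54520.6488421172,48302.212033059,10,0,FALSE
SSEDPNEDIVER,P002_B,rep1,y4,151444.551359753,120314.08443531,10,0,FALSE
SSEDPNEDIVER,P002_B,rep1,y5,153237.31240253,130081.745997329,10,0,FALSE
SSEDPNEDIVER,P002_B,rep1,y6,156915.447760396,133675.526037387,10,0,FALSE
SSEDPNEDIVER,P002_B,rep2,y4,58308.8516546981,48322.6408977046,10,0,FALSE
SSEDPNEDIVER,P002_B,rep2,y5,98353.5560417745,88696.1755666526,10,0,FALSE
SSEDPNEDIVER,P002_B,rep2,y6,117832.774345208,95567.4807802496,10,0,FALSE
SSEDPNEDIVER,P003_B,rep1,y4,73868.4481820073,84503.0303379316,10,0,FALSE
SSEDPNEDIVER,P003_B,rep1,y5,78613.9745043065,91117.9547825313,10,0,FALSE
SSEDPNEDIVER,P003_B,rep1,y6,60023.7396869516,68950.435627515,10,0,FALSE
SSEDPNEDIVER,P003_B,rep2,y4,200883.607608841,243255.693938737,10,0,FALSE
SSEDPNEDIVER,P003_B,rep2,y5,44692.5100599196,53291.3465617617,10,0,FALSE
SSEDPNEDIVER,P003_B,rep2,y6,87511.3043804006,93181.3844824457,10,0,FALSE
SSEDPNEDIVER,P004_B,rep1,y4,140638.415624098,140923.924013189,10,0,FALSE
SSEDPNEDIVER,P004_B,rep1,y5,142060.502712096,146361.517768672,10,0,FALSE
SSEDPNEDIVER,P004_B,rep1,y6,121457.733873897,132871.621889763,10,0,FALSE
SSEDPNEDIVER,P004_B,rep2,y4,46874.8343169903,52085.8829577732,10,0,FALSE
SSEDPNEDIVER,P004_B,rep2,y5,114756.720417636,120040.072360769,10,0,FALSE
SSEDPNEDIVER,P004_B,rep2,y6,91871.220874899,94002.1662908109,10,0,FALSE
SSEDPNEDIVER,P001_F,rep1,y4,37092.921999955,56999.6952363308,10,0,FALSE
SSEDPNEDIVER,P001_F,rep1,y5,70174.5232718564,125764.715180794,10,0,FALSE
SSEDPNEDIVER,P001_F,rep1,y6,177911.265340252,258657.901975758,10,0,FALSE
SSEDPNEDIVER,P001_F,rep2,y4,16623.5599198293,27761.0845533718,10,0,FALSE
SSEDPNEDIVER,P001_F,rep2,y5,96699.0016766478,157562.658326428,10,0,FALSE
SSEDPNEDIVER,P001_F,rep2,y6,49855.4332200518,84245.8820169249,10,0,FALSE
SSEDPNEDIVER,P002_F,rep1,y4,115605.287607953,182613.165128206,10,0,FALSE
SSEDPNEDIVER,P002_F,rep1,y5,41601.0836614154,68330.097150313,10,0,FALSE
SSEDPNEDIVER,P002_F,rep1,y6,117833.61129638,166317.277176298,10,0,FALSE
SSEDPNEDIVER,P002_F,rep2,y4,108455.202241945,164515.458788458,10,0,FALSE
SSEDPNEDIVER,P002_F,rep2,y5,23900.1130580728,36444.1102632173,10,0,FALSE
SSEDPNEDIVER,P002_F,rep2,y6,111155.133988734,176778.458675821,10,0,FALSE
SSEDPNEDIVER,P003_F,rep1,y4,39441.3938196547,83988.7669870243,10,0,FALSE
SSEDPNEDIVER,P003_F,rep1,y5,35806.5871799434,80367.857793182,10,0,FALSE
SSEDPNEDIVER,P003_F,rep1,y6,19637.5034229495,41656.904307001,10,0,FALSE
SSEDPNEDIVER,P003_F,rep2,y4,52549.3490038392,112065.330125715,10,0,FALSE
SSEDPNEDIVER,P003_F,rep2,y5,19273.9262867186,42753.4960033708,10,0,FALSE
SSEDPNEDIVER,P003_F,rep2,y6,63397.0842862194,141793.040163953,10,0,FALSE
SSEDPNEDIVER,P004_F,rep1,y4,47856.1546772551,119359.481092887,10,0,FALSE
SSEDPNEDIVER,P004_F,rep1,y5,30908.6551600277,75251.0918141395,10,0,FALSE
SSEDPNEDIVER,P004_F,rep1,y6,31991.4509900674,85963.1111666453,10,0,FALSE
SSEDPNEDIVER,P004_F,rep2,y4,25560.4641157893,61673.0869959916,10,0,FALSE
SSEDPNEDIVER,P004_F,rep2,y5,43119.5848563213,108664.523915148,10,0,FALSE
SSEDPNEDIVER,P004_F,rep2,y6,78572.133226717,196667.690162679,10,0,FALSE
AGDFLEANYMNLQR,P001_B,rep1,y4,149653.695729734,85436.8433648996,10,0,FALSE
AGDFLEANYMNLQR,P001_B,rep1,y5,75390.2821457125,46681.09552721,10,0,FALSE
AGDFLEANYMNLQR,P001_B,rep1,y6,351439.02475834,209494.359950024,10,0,FALSE
AGDFLEANYMNLQR,P001_B,rep2,y4,113290.678642566,64862.0891117014,10,0,FALSE
AGDFLEANYMNLQR,P001_B,rep2,y5,179881.415627441,108219.918812856,10,0,FALSE
AGDFLEANYMNLQR,P001_B,rep2,y6,130537.777442101,72203.0763327575,10,0,FALSE
AGDFLEANYMNLQR,P002_B,rep1,y4,287222.126300908,124363.16383717,10,0,FALSE
AGDFLEANYMNLQR,P002_B,rep1,y5,266999.954407716,113078.59964173,10,0,FALSE
AGDFLEANYMNLQR,P002_B,rep1,y6,201251.880100693,86275.062461991,10,0,FALSE
AGDFLEANYMNLQR,P002_B,rep2,y4,306433.344350373,134099.537101611,10,0,FALSE
AGDFLEANYMNLQR,P002_B,rep2,y5,169673.506177522,67859.4709548966,10,0,FALSE
AGDFLEANYMNLQR,P002_B,rep2,y6,195687.789352818,84561.0802342444,10,0,FALSE
AGDFLEANYMNLQR,P003_B,rep1,y4,139917.320285194,88441.5232284544,10,0,FALSE
AGDFLEANYMNLQR,P003_B,rep1,y5,44008.000482207,26673.742192997,10,0,FALSE
AGDFLEANYMNLQR,P003_B,rep1,y6,110439.963838703,68328.2996455842,10,0,FALSE
AGDFLEANYMNLQR,P003_B,rep2,y4,104744.714984023,64169.4919036646,10,0,FALSE
AGDFLEANYMNLQR,P003_B,rep2,y5,373026.993716929,238033.856133262,10,0,FALSE
AGDFLEANYMNLQR,P003_B,rep2,y6,125139.407473775,79500.5808055758,10,0,FALSE
AGDFLEANYMNLQR,P004_B,rep1,y4,83032.9956189655,53799.2609419396,10,0,FALSE
AGDFLEANYMNLQR,P004_B,rep1,y5,179895.783668368,125095.039216138,10,0,FALSE
AGDFLEANYMNLQR,P004_B,rep1,y6,186763.244116859,127420.063531947,10,0,FALSE
AGDFLEANYMNLQR,P004_B,rep2,y4,140538.447781047,100666.227578769,10,0,FALSE
AGDFLEANYMNLQR,P004_B,rep2,y5,87596.4123519338,64808.9976868812,10,0,FALSE
AGDFLEANYMNLQR,P004_B,rep2,y6,98507.9573404648,69946.5177326966,10,0,FALSE
AGDFLEANYMNLQR,P001_F,rep1,y4,225504.589197369,77256.6113319038,10,0,FALSE
AGDFLEANYMNLQR,P001_F,rep1,y5,151296.898055347,48093.7737128156,10,0,FALSE
AGDFLEANYMNLQR,P001_F,rep1,y6,379928.387764662,119138.722907852,10,0,FALSE
AGDFLEANYMNLQR,P001_F,rep2,y4,190860.57600001,61193.3687364188,10,0,FALSE
AGDFLEANYMNLQR,P001_F,rep2,y5,148636.228592835,48010.2908609,10,0,FALSE
AGDFLEANYMNLQR,P001_F,rep2,y6,266299.060070565,84021.8108103671,10,0,FALSE
AGDFLEANYMNLQR,P002_F,rep1,y4,225356.975778077,79665.2948253425,10,0,FALSE
AGDFLEANYMNLQR,P002_F,rep1,y5,450787.586333138,162727.508913773,10,0,FALSE
AGDFLEANYMNLQR,P002_F,rep1,y6,501984.525941451,169848.27143573,10,0,FALSE
AGDFLEANYMNLQR,P002_F,rep2,y4,187133.340920825,69635.7141807494,10,0,FALSE
AGDFLEANYMNLQR,P002_F,rep2,y5,362738.108860933,128929.743434038,10,0,FALSE
AGDFLEANYMNLQR,P002_F,rep2,y6,636156.68623635,226124.787086993,10,0,FALSE
AGDFLEANYMNLQR,P003_F,rep1,y4,141172.628422709,87215.0770033401,10,0,FALSE
AGDFLEANYMNLQR,P003_F,rep1,y5,205086.906491314,117903.828991487,10,0,FALSE
AGDFLEANYMNLQR,P003_F,rep1,y6,211208.953285968,118896.333772925,10,0,FALSE
AGDFLEANYMNLQR,P003_F,rep2,y4,85582.3680780093,49290.6427354522,10,0,FALSE
AGDFLEANYMNLQR,P003_F,rep2,y5,48214.5439581334,28024.1437359544,10,0,FALSE
AGDFLEANYMNLQR,P003_F,rep2,y6,235742.025285795,129732.92971707,10,0,FALSE
AGDFLEANYMNLQR,P004_F,rep1,y4,247028.942671871,98704.6175642231,10,0,FALSE
AGDFLEANYMNLQR,P004_F,rep1,y5,229630.13653724,81944.1861291567,10,0,FALSE
AGDFLEANYMNLQR,P004_F,rep1,y6,203598.605951011,75047.1722277998,10,0,FALSE
AGDFLEANYMNLQR,P004_F,rep2,y4,584523.418289271,203299.133318612,10,0,FALSE
AGDFLEANYMNLQR,P004_F,rep2,y5,130149.000625156,49081.4681077267,10,0,FALSE
AGDFLEANYMNLQR,P004_F,rep2,y6,122666.769184481,46911.6828021083,10,0,FALSE
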