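peptide_sequence,theoretical_conc,ratio_to_standard,replicate_id,dilution_factor
SSEDPNEDIVER,8,8.3257057276855,cal_rep1,8
SSEDPNEDIVER,4,4.02697718941497,cal_rep1,4
SSEDPNEDIVER,2,1.98576717007675,cal_rep1,2
SSEDPNEDIVER,1,0.99313144803397,cal_rep1,1
SSEDPNEDIVER,0.5,0.490274051753448,cal_rep1,0.5
SSEDPNEDIVER,0.25,0.284221181953605,cal_rep1,0.25
SSEDPNEDIVER,0.12,0.134613126145876,cal_rep1,0.12
SSEDPNEDIVER,0.06,0.0822323451662635,cal_rep1,0.06
SSEDPNEDIVER,0.03,0.0493365377151529,cal_rep1,0.03
SSEDPNEDIVER,8,8.69248879196767,cal_rep2,8
SSEDPNEDIVER,4,3.97343833735718,cal_rep2,4
SSEDPNEDIVER,2,1.93069634149916,cal_rep2,2
SSEDPNEDIVER,1,0.990002196557584,cal_rep2,1
SSEDPNEDIVER,0.5,0.519031383382846,cal_rep2,0.5
SSEDPNEDIVER,0.25,0.251019249502769,cal_rep2,0.25
SSEDPNEDIVER,0.12,0.133111846656842,cal_rep2,0.12
SSEDPNEDIVER,0.06,0.0805563065912378,cal_rep2,0.06
SSEDPNEDIVER,0.03,0.0531829073879414,cal_rep2,0.03
AGDFLEANYMNLQR,16,16.9461804015289,cal_rep1,8
AGDFLEANYMNLQR,8,7.72600107467039,cal_rep1,4
AGDFLEANYMNLQR,4,4.35098469596278,cal_rep1,2
AGDFLEANYMNLQR,2,1.98274725970076,cal_rep1,1
AGDFLEANYMNLQR,1,0.965486068222365,cal_rep1,0.5
AGDFLEANYMNLQR,0.5,0.53778454300645,cal_rep1,0.25
AGDFLEANYMNLQR,0.24,0.271586128987242,cal_rep1,0.12
AGDFLEANYMNLQR,0.12,0.132071472136395,cal_rep1,0.06
AGDFLEANYMNLQR,0.06,0.0804862306812393,cal_rep1,0.03
AGDFLEANYMNLQR,16,16.0096540046355,cal_rep2,8
AGDFLEANYMNLQR,8,8.25229991189589,cal_rep2,4
AGDFLEANYMNLQR,4,4.01543248537818,cal_rep2,2
AGDFLEANYMNLQR,2,2.15441017202747,cal_rep2,1
AGDFLEANYMNLQR,1,0.93116341228473,cal_rep2,0.5
AGDFLEANYMNLQR,0.5,0.55094635171272,cal_rep2,0.25
AGDFLEANYMNLQR,0.24,0.268276124043436,cal_rep2,0.12
AGDFLEANYMNLQR,0.12,0.142894227640196,cal_rep2,0.06
AGDFLEANYMNLQR,0.06,0.0842750739562765,cal_rep2,0.03
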