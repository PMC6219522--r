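patient_id,drugs,observed,carboplatin,paclitaxel,cisplatin,gemcitabine,docetaxel,doxorubicin,gefitinib,topotecan
229,carboplatin;gemcitabine,R,NR,NR,R,R,R,NR,NR,NR
242,carboplatin;paclitaxel,R,R,NR,NR,NR,R,R,R,NR
272,carboplatin;paclitaxel,NR,NR,R,NR,R,R,NR,NR,NR
286,carboplatin;paclitaxel,NR,NR,NR,NR,NR,NR,R,R,NR
317,carboplatin;paclitaxel,R,R,R,R,R,NR,R,NR,NR
336,carboplatin;paclitaxel,R,R,R,R,R,R,NR,NR,NR
367,carboplatin;paclitaxel,R,R,R,NR,R,NR,NR,NR,NR
413,carboplatin;paclitaxel,R,R,R,NR,R,R,R,NR,NR
489,carboplatin;paclitaxel,R,R,R,NR,NR,NR,NR,NR,R
528,carboplatin;paclitaxel,R,R,R,NR,NR,R,NR,NR,NR
542,carboplatin;paclitaxel,R,R,R,NR,R,NR,NR,NR,NR
545,carboplatin;paclitaxel,NR,NR,NR,NR,R,R,NR,NR,R
588,carboplatin;paclitaxel,R,R,NR,R,R,R,NR,NR,R
617,carboplatin;paclitaxel,R,R,R,NR,R,NR,NR,NR,NR
620,carboplatin;paclitaxel,R,R,R,NR,R,NR,NR,NR,NR
813,carboplatin;cisplatin;paclitaxel,R,NR,R,R,NR,NR,NR,NR,NR
992,topotecan,NR,R,NR,NR,R,NR,NR,NR,NR
1012,carboplatin;docetaxel,R,NR,NR,R,R,R,R,NR,NR
1122,carboplatin;paclitaxel,R,NR,R,NR,R,NR,NR,NR,NR
1129,doxorubicin,R,NR,R,R,R,NR,R,NR,NR
1145,carboplatin;paclitaxel,NR,R,NR,NR,NR,NR,NR,NR,R
BJ1,carboplatin;paclitaxel,R,NR,NR,R,R,NR,NR,NR,NR
BJ4,carboplatin;paclitaxel,R,NR,R,R,R,R,R,NR,NR
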