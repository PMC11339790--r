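dataset,modality,item,n0,n1
LOCAL_1,cfp,ic,158,41
LOCAL_1,cfp,blur,94,105
LOCAL_1,cfp,lc,85,114
LOCAL_1,cfp,overall,142,57
LOCAL_2,cfp,ic,78,25
LOCAL_2,cfp,blur,59,44
LOCAL_2,cfp,lc,41,62
LOCAL_2,cfp,overall,77,26
DR_1,cfp,ic,31,156
DR_1,cfp,blur,34,153
DR_1,cfp,lc,6,181
DR_1,cfp,overall,40,147
DR_2,cfp,ic,36,199
DR_2,cfp,blur,120,115
DR_2,cfp,lc,78,157
DR_2,cfp,overall,117,118
GLU,cfp,ic,45,7
GLU,cfp,blur,48,4
GLU,cfp,lc,42,10
GLU,cfp,overall,50,2
NORMAL,cfp,ic,2,24
NORMAL,cfp,blur,0,26
NORMAL,cfp,lc,0,26
NORMAL,cfp,overall,0,26
DRIMDB,cfp,ic,54,140
DRIMDB,cfp,blur,74,120
DRIMDB,cfp,lc,76,118
DRIMDB,cfp,overall,70,124
DRIVE,cfp,ic,0,40
DRIVE,cfp,blur,0,40
DRIVE,cfp,lc,0,40
DRIVE,cfp,overall,0,40
DR_UWF,uwf,ic,215,285
DR_UWF,uwf,blur,163,337
DR_UWF,uwf,lc,50,450
DR_UWF,uwf,overall,168,332
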