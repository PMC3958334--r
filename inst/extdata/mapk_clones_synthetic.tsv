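clone	I	II	III	IV	V	VI	VII	VIII
ctrl_01	1	1	1	1	1	1	1	1
caperKD_01	1	1	1	0	1	1	1	1
caperKD_02	1	1	1	1	1	1	0	1
prp19KD_01	1	1	1	0	1	1	0	1
ejcKD_01	1	0	1	1	1	1	1	1
ejcKD_02	1	0	0	1	1	1	1	1
prp19KD_02	1	1	0	1	1	1	1	1
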