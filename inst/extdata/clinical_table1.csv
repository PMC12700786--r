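patient_id,age,sex,months_since_op,dbs_target,ipg_side,ygtss_tts,ygtss_global,puts
P1,27,M,26,CM_Voi,right,34,54,49
P2,33,M,85,CM_Voi,right,14,14,30
P3,27,M,3,CM_Voi,left,25,45,41
P6,24,M,3,CM_Voi,left,20,40,43
P7,38,M,164,VA_VL,left,21,41,35
P8,35,M,104,CM_Voi,left,11,36,22
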