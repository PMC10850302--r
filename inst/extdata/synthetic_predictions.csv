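chemical_id,model_id,prediction
chem00001,mA,out_of_domain
chem00002,mA,inactive
chem00003,mA,active
chem00004,mA,active
chem00005,mA,active
chem00006,mA,active
chem00007,mA,active
chem00008,mA,inactive
chem00009,mA,inactive
chem00010,mA,inactive
chem00011,mA,active
chem00012,mA,inactive
chem00013,mA,out_of_domain
chem00014,mA,active
chem00015,mA,active
chem00016,mA,inactive
chem00017,mA,inactive
chem00018,mA,inactive
chem00019,mA,active
chem00020,mA,inactive
chem00021,mA,inactive
chem00022,mA,inactive
chem00023,mA,inactive
chem00024,mA,inactive
chem00025,mA,active
chem00026,mA,inactive
chem00027,mA,inactive
chem00028,mA,inactive
chem00029,mA,inactive
chem00030,mA,active
chem00031,mA,out_of_domain
chem00032,mA,inactive
chem00033,mA,inactive
chem00034,mA,inactive
chem00035,mA,active
chem00036,mA,inactive
chem00037,mA,inactive
chem00038,mA,inactive
chem00039,mA,active
chem00040,mA,inactive
chem00001,mB,active
chem00002,mB,out_of_domain
chem00003,mB,inactive
chem00004,mB,inactive
chem00005,mB,active
chem00006,mB,out_of_domain
chem00007,mB,active
chem00008,mB,inactive
chem00009,mB,out_of_domain
chem00010,mB,inactive
chem00011,mB,active
chem00012,mB,active
chem00013,mB,out_of_domain
chem00014,mB,active
chem00015,mB,active
chem00016,mB,out_of_domain
chem00017,mB,inactive
chem00018,mB,out_of_domain
chem00019,mB,active
chem00020,mB,active
chem00021,mB,inactive
chem00022,mB,inactive
chem00023,mB,inactive
chem00024,mB,inactive
chem00025,mB,inactive
chem00026,mB,inactive
chem00027,mB,out_of_domain
chem00028,mB,inactive
chem00029,mB,inactive
chem00030,mB,inactive
chem00031,mB,active
chem00032,mB,inactive
chem00033,mB,active
chem00034,mB,active
chem00035,mB,active
chem00036,mB,active
chem00037,mB,inactive
chem00038,mB,active
chem00039,mB,active
chem00040,mB,active
chem00001,mC,inactive
chem00002,mC,out_of_domain
chem00003,mC,inactive
chem00004,mC,inactive
chem00005,mC,active
chem00006,mC,out_of_domain
chem00007,mC,out_of_domain
chem00008,mC,inactive
chem00009,mC,inactive
chem00010,mC,out_of_domain
chem00011,mC,active
chem00012,mC,out_of_domain
chem00013,mC,inactive
chem00014,mC,out_of_domain
chem00015,mC,active
chem00016,mC,active
chem00017,mC,inactive
chem00018,mC,inactive
chem00019,mC,out_of_domain
chem00020,mC,out_of_domain
chem00021,mC,active
chem00022,mC,out_of_domain
chem00023,mC,out_of_domain
chem00024,mC,out_of_domain
chem00025,mC,out_of_domain
chem00026,mC,active
chem00027,mC,active
chem00028,mC,out_of_domain
chem00029,mC,inactive
chem00030,mC,out_of_domain
chem00031,mC,inactive
chem00032,mC,out_of_domain
chem00033,mC,inactive
chem00034,mC,out_of_domain
chem00035,mC,inactive
chem00036,mC,out_of_domain
chem00037,mC,out_of_domain
chem00038,mC,out_of_domain
chem00039,mC,active
chem00040,mC,inactive
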