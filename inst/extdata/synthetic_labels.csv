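chemical_id,label
chem00001,inactive
chem00002,inactive
chem00003,active
chem00004,inactive
chem00005,active
chem00006,inactive
chem00007,active
chem00008,inactive
chem00009,inactive
chem00010,inactive
chem00011,active
chem00012,inactive
chem00013,inactive
chem00014,active
chem00015,active
chem00016,inactive
chem00017,inactive
chem00018,inactive
chem00019,active
chem00020,inactive
chem00021,inactive
chem00022,inactive
chem00023,inactive
chem00024,inactive
chem00025,inactive
chem00026,inactive
chem00027,inactive
chem00028,inactive
chem00029,inactive
chem00030,inactive
chem00031,active
chem00032,inactive
chem00033,active
chem00034,inactive
chem00035,active
chem00036,inactive
chem00037,inactive
chem00038,inactive
chem00039,active
chem00040,inactive
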