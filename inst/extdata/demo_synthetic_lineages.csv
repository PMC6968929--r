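lineage_id,method,area,age,l23,l4,l5,l6
S1-001,genetic,S1,P21,5,0,3,3
S1-002,genetic,S1,P21,1,2,1,3
S1-003,genetic,S1,P21,0,1,4,1
S1-004,genetic,S1,P21,3,1,0,0
S1-005,genetic,S1,P21,0,1,1,1
S1-006,genetic,S1,P21,3,0,4,4
S1-007,genetic,S1,P21,0,1,3,2
S1-008,genetic,S1,P21,2,2,0,0
S1-009,genetic,S1,P21,2,1,2,1
S1-010,genetic,S1,P21,0,1,3,2
S1-011,genetic,S1,P21,2,1,1,1
S1-012,genetic,S1,P21,1,1,1,3
S1-013,genetic,S1,P21,0,0,0,3
S1-014,genetic,S1,P21,2,2,0,0
S1-015,genetic,S1,P21,3,0,3,4
S1-016,genetic,S1,P21,1,1,1,3
S1-017,genetic,S1,P21,1,2,0,0
S1-018,genetic,S1,P21,3,2,1,0
S1-019,genetic,S1,P21,0,0,3,2
S1-020,genetic,S1,P21,3,1,4,4
S1-021,genetic,S1,P21,1,1,4,4
S1-022,genetic,S1,P21,0,0,1,2
S1-023,genetic,S1,P21,4,2,3,2
S1-024,genetic,S1,P21,1,2,3,4
S1-025,genetic,S1,P21,1,2,0,0
S1-026,genetic,S1,P21,2,1,2,3
S1-027,genetic,S1,P21,1,2,0,0
S1-028,genetic,S1,P21,2,0,4,3
S1-029,genetic,S1,P21,0,1,1,4
S1-030,genetic,S1,P21,2,1,4,1
S1-031,genetic,S1,P21,3,1,1,3
S1-032,genetic,S1,P21,1,2,2,2
S1-033,genetic,S1,P21,2,0,1,1
S1-034,genetic,S1,P21,3,2,0,0
S1-035,genetic,S1,P21,4,0,3,3
S1-036,genetic,S1,P21,3,1,0,0
S1-037,genetic,S1,P21,3,0,3,3
S1-038,genetic,S1,P21,3,1,4,1
S1-039,genetic,S1,P21,2,1,2,4
S1-040,genetic,S1,P21,1,1,2,4
S1-041,genetic,S1,P21,3,1,2,4
S1-042,genetic,S1,P21,2,1,0,0
S1-043,genetic,S1,P21,2,1,0,0
S1-044,genetic,S1,P21,0,1,4,2
S1-045,genetic,S1,P21,2,1,4,3
S1-046,genetic,S1,P21,0,2,4,4
S1-047,genetic,S1,P21,1,1,3,3
S1-048,genetic,S1,P21,3,1,4,3
S1-049,genetic,S1,P21,2,1,3,1
S1-050,genetic,S1,P21,4,2,3,3
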