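timestamp,masennus,depression test
2017-03-01T00,66,50
2017-03-01T01,68,51
2017-03-01T02,67,52
2017-03-01T03,65,53
2017-03-01T04,64,47
2017-03-01T05,65,47
2017-03-01T06,66,46
2017-03-01T07,63,38
2017-03-01T08,56,35
2017-03-01T09,53,37
2017-03-01T10,42,39
2017-03-01T11,44,32
2017-03-01T12,44,28
2017-03-01T13,41,31
2017-03-01T14,43,<1
2017-03-01T15,39,36
2017-03-01T16,47,35
2017-03-01T17,42,32
2017-03-01T18,54,37
2017-03-01T19,52,41
2017-03-01T20,55,37
2017-03-01T21,55,42
2017-03-01T22,73,51
2017-03-01T23,66,44
2017-03-02T00,60,50
2017-03-02T01,66,53
2017-03-02T02,68,54
2017-03-02T03,73,50
2017-03-02T04,72,53
2017-03-02T05,67,45
2017-03-02T06,59,45
2017-03-02T07,57,42
2017-03-02T08,53,35
2017-03-02T09,41,32
2017-03-02T10,46,30
2017-03-02T11,49,35
2017-03-02T12,41,30
2017-03-02T13,36,32
2017-03-02T14,35,31
2017-03-02T15,44,35
2017-03-02T16,38,30
2017-03-02T17,43,36
2017-03-02T18,48,37
2017-03-02T19,55,41
2017-03-02T20,57,41
2017-03-02T21,60,49
2017-03-02T22,66,54
2017-03-02T23,62,45
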