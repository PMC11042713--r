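station,date,depth_cm
APP,2016-11-01,0
APP,2016-11-02,0
APP,2016-11-03,0
APP,2016-11-04,0
APP,2016-11-05,0
APP,2016-11-06,0
APP,2016-11-07,0
APP,2016-11-08,0
APP,2016-11-09,0
APP,2016-11-10,15
APP,2016-11-11,15
APP,2016-11-12,15
APP,2016-11-13,15
APP,2016-11-14,15
APP,2016-11-15,15
APP,2016-11-16,15
APP,2016-11-17,15
APP,2016-11-18,15
APP,2016-11-19,15
APP,2016-11-20,15
APP,2016-11-21,15
APP,2016-11-22,15
APP,2016-11-23,15
APP,2016-11-24,15
APP,2016-11-25,15
APP,2016-11-26,15
APP,2016-11-27,15
APP,2016-11-28,15
APP,2016-11-29,15
APP,2016-11-30,15
APP,2016-12-01,35
APP,2016-12-02,35
APP,2016-12-03,35
APP,2016-12-04,35
APP,2016-12-05,35
APP,2016-12-06,35
APP,2016-12-07,35
APP,2016-12-08,35
APP,2016-12-09,35
APP,2016-12-10,35
APP,2016-12-11,35
APP,2016-12-12,35
APP,2016-12-13,35
APP,2016-12-14,35
APP,2016-12-15,35
APP,2016-12-16,35
APP,2016-12-17,35
APP,2016-12-18,35
APP,2016-12-19,35
APP,2016-12-20,35
APP,2016-12-21,35
APP,2016-12-22,35
APP,2016-12-23,35
APP,2016-12-24,35
APP,2016-12-25,35
APP,2016-12-26,35
APP,2016-12-27,35
APP,2016-12-28,35
APP,2016-12-29,35
APP,2016-12-30,35
APP,2016-12-31,35
APP,2017-01-01,35
APP,2017-01-02,35
APP,2017-01-03,35
APP,2017-01-04,35
APP,2017-01-05,35
APP,2017-01-06,35
APP,2017-01-07,35
APP,2017-01-08,35
APP,2017-01-09,35
APP,2017-01-10,35
APP,2017-01-11,35
APP,2017-01-12,35
APP,2017-01-13,35
APP,2017-01-14,35
APP,2017-01-15,35
APP,2017-01-16,35
APP,2017-01-17,35
APP,2017-01-18,35
APP,2017-01-19,35
APP,2017-01-20,35
APP,2017-01-21,35
APP,2017-01-22,35
APP,2017-01-23,35
APP,2017-01-24,35
APP,2017-01-25,35
APP,2017-01-26,35
APP,2017-01-27,35
APP,2017-01-28,35
APP,2017-01-29,35
APP,2017-01-30,35
APP,2017-01-31,35
APP,2017-02-01,35
APP,2017-02-02,35
APP,2017-02-03,35
APP,2017-02-04,35
APP,2017-02-05,35
APP,2017-02-06,35
APP,2017-02-07,35
APP,2017-02-08,35
APP,2017-02-09,35
APP,2017-02-10,35
APP,2017-02-11,35
APP,2017-02-12,35
APP,2017-02-13,35
APP,2017-02-14,35
APP,2017-02-15,35
APP,2017-02-16,35
APP,2017-02-17,35
APP,2017-02-18,35
APP,2017-02-19,35
APP,2017-02-20,35
APP,2017-02-21,35
APP,2017-02-22,35
APP,2017-02-23,35
APP,2017-02-24,35
APP,2017-02-25,35
APP,2017-02-26,35
APP,2017-02-27,35
APP,2017-02-28,35
APP,2017-03-01,35
APP,2017-03-02,35
APP,2017-03-03,35
APP,2017-03-04,35
APP,2017-03-05,35
APP,2017-03-06,35
APP,2017-03-07,35
APP,2017-03-08,35
APP,2017-03-09,35
APP,2017-03-10,35
APP,2017-03-11,35
APP,2017-03-12,35
APP,2017-03-13,35
APP,2017-03-14,35
APP,2017-03-15,35
APP,2017-03-16,35
APP,2017-03-17,35
APP,2017-03-18,35
APP,2017-03-19,35
APP,2017-03-20,35
APP,2017-03-21,35
APP,2017-03-22,35
APP,2017-03-23,35
APP,2017-03-24,35
APP,2017-03-25,35
APP,2017-03-26,35
APP,2017-03-27,35
APP,2017-03-28,35
APP,2017-03-29,35
APP,2017-03-30,35
APP,2017-03-31,35
APP,2017-04-01,30
APP,2017-04-02,30
APP,2017-04-03,30
APP,2017-04-04,30
APP,2017-04-05,30
APP,2017-04-06,30
APP,2017-04-07,30
APP,2017-04-08,30
APP,2017-04-09,30
APP,2017-04-10,30
APP,2017-04-11,0
APP,2017-04-12,0
APP,2017-04-13,0
APP,2017-04-14,0
APP,2017-04-15,0
APP,2017-04-16,0
APP,2017-04-17,0
APP,2017-04-18,0
APP,2017-04-19,0
APP,2017-04-20,0
APP,2017-04-21,0
APP,2017-04-22,0
APP,2017-04-23,0
APP,2017-04-24,0
APP,2017-04-25,0
APP,2017-04-26,0
APP,2017-04-27,0
APP,2017-04-28,0
APP,2017-04-29,0
APP,2017-04-30,0
NON,2016-11-01,0
NON,2016-11-02,0
NON,2016-11-03,0
NON,2016-11-04,0
NON,2016-11-05,0
NON,2016-11-06,0
NON,2016-11-07,0
NON,2016-11-08,0
NON,2016-11-09,0
NON,2016-11-10,20
NON,2016-11-11,20
NON,2016-11-12,20
NON,2016-11-13,20
NON,2016-11-14,20
NON,2016-11-15,20
NON,2016-11-16,20
NON,2016-11-17,20
NON,2016-11-18,20
NON,2016-11-19,20
NON,2016-11-20,20
NON,2016-11-21,20
NON,2016-11-22,20
NON,2016-11-23,20
NON,2016-11-24,20
NON,2016-11-25,20
NON,2016-11-26,20
NON,2016-11-27,20
NON,2016-11-28,20
NON,2016-11-29,20
NON,2016-11-30,20
NON,2016-12-01,45
NON,2016-12-02,45
NON,2016-12-03,45
NON,2016-12-04,45
NON,2016-12-05,45
NON,2016-12-06,45
NON,2016-12-07,45
NON,2016-12-08,45
NON,2016-12-09,45
NON,2016-12-10,45
NON,2016-12-11,45
NON,2016-12-12,45
NON,2016-12-13,45
NON,2016-12-14,45
NON,2016-12-15,45
NON,2016-12-16,45
NON,2016-12-17,45
NON,2016-12-18,45
NON,2016-12-19,45
NON,2016-12-20,45
NON,2016-12-21,45
NON,2016-12-22,45
NON,2016-12-23,45
NON,2016-12-24,45
NON,2016-12-25,45
NON,2016-12-26,45
NON,2016-12-27,45
NON,2016-12-28,45
NON,2016-12-29,45
NON,2016-12-30,45
NON,2016-12-31,45
NON,2017-01-01,45
NON,2017-01-02,45
NON,2017-01-03,45
NON,2017-01-04,45
NON,2017-01-05,45
NON,2017-01-06,45
NON,2017-01-07,45
NON,2017-01-08,45
NON,2017-01-09,45
NON,2017-01-10,45
NON,2017-01-11,45
NON,2017-01-12,45
NON,2017-01-13,45
NON,2017-01-14,45
NON,2017-01-15,45
NON,2017-01-16,45
NON,2017-01-17,45
NON,2017-01-18,45
NON,2017-01-19,45
NON,2017-01-20,45
NON,2017-01-21,45
NON,2017-01-22,45
NON,2017-01-23,45
NON,2017-01-24,45
NON,2017-01-25,45
NON,2017-01-26,45
NON,2017-01-27,45
NON,2017-01-28,45
NON,2017-01-29,45
NON,2017-01-30,45
NON,2017-01-31,45
NON,2017-02-01,45
NON,2017-02-02,45
NON,2017-02-03,45
NON,2017-02-04,45
NON,2017-02-05,45
NON,2017-02-06,45
NON,2017-02-07,45
NON,2017-02-08,45
NON,2017-02-09,45
NON,2017-02-10,45
NON,2017-02-11,45
NON,2017-02-12,45
NON,2017-02-13,45
NON,2017-02-14,45
NON,2017-02-15,45
NON,2017-02-16,45
NON,2017-02-17,45
NON,2017-02-18,45
NON,2017-02-19,45
NON,2017-02-20,45
NON,2017-02-21,45
NON,2017-02-22,45
NON,2017-02-23,45
NON,2017-02-24,45
NON,2017-02-25,45
NON,2017-02-26,45
NON,2017-02-27,45
NON,2017-02-28,45
NON,2017-03-01,45
NON,2017-03-02,45
NON,2017-03-03,45
NON,2017-03-04,45
NON,2017-03-05,45
NON,2017-03-06,45
NON,2017-03-07,45
NON,2017-03-08,45
NON,2017-03-09,45
NON,2017-03-10,45
NON,2017-03-11,45
NON,2017-03-12,45
NON,2017-03-13,45
NON,2017-03-14,45
NON,2017-03-15,45
NON,2017-03-16,45
NON,2017-03-17,45
NON,2017-03-18,45
NON,2017-03-19,45
NON,2017-03-20,45
NON,2017-03-21,45
NON,2017-03-22,45
NON,2017-03-23,45
NON,2017-03-24,45
NON,2017-03-25,45
NON,2017-03-26,45
NON,2017-03-27,45
NON,2017-03-28,45
NON,2017-03-29,45
NON,2017-03-30,45
NON,2017-03-31,45
NON,2017-04-01,25
NON,2017-04-02,25
NON,2017-04-03,25
NON,2017-04-04,25
NON,2017-04-05,25
NON,2017-04-06,25
NON,2017-04-07,25
NON,2017-04-08,25
NON,2017-04-09,25
NON,2017-04-10,25
NON,2017-04-11,25
NON,2017-04-12,25
NON,2017-04-13,25
NON,2017-04-14,25
NON,2017-04-15,25
NON,2017-04-16,0
NON,2017-04-17,0
NON,2017-04-18,0
NON,2017-04-19,0
NON,2017-04-20,0
NON,2017-04-21,0
NON,2017-04-22,0
NON,2017-04-23,0
NON,2017-04-24,0
NON,2017-04-25,0
NON,2017-04-26,0
NON,2017-04-27,0
NON,2017-04-28,0
NON,2017-04-29,0
NON,2017-04-30,0
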