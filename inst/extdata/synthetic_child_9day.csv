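day_hour,steps
2021-11-01T06:00,130
2021-11-01T07:00,100
2021-11-01T08:00,166
2021-11-01T09:00,386
2021-11-01T10:00,259
2021-11-01T11:00,411
2021-11-01T12:00,243
2021-11-01T13:00,372
2021-11-01T14:00,310
2021-11-01T15:00,405
2021-11-01T16:00,676
2021-11-01T17:00,930
2021-11-01T18:00,324
2021-11-01T19:00,462
2021-11-01T20:00,191
2021-11-01T21:00,157
2021-11-01T22:00,131
2021-11-01T23:00,117
2021-11-02T06:00,124
2021-11-02T07:00,170
2021-11-02T08:00,345
2021-11-02T09:00,299
2021-11-02T10:00,45
2021-11-02T11:00,551
2021-11-02T12:00,77
2021-11-02T13:00,294
2021-11-02T14:00,599
2021-11-02T15:00,416
2021-11-02T16:00,502
2021-11-02T17:00,719
2021-11-02T18:00,85
2021-11-02T19:00,551
2021-11-02T20:00,110
2021-11-02T21:00,71
2021-11-02T22:00,145
2021-11-02T23:00,26
2021-11-03T06:00,118
2021-11-03T07:00,112
2021-11-03T08:00,430
2021-11-03T09:00,242
2021-11-03T10:00,242
2021-11-03T11:00,491
2021-11-03T12:00,144
2021-11-03T13:00,221
2021-11-03T14:00,511
2021-11-03T15:00,309
2021-11-03T16:00,784
2021-11-03T17:00,139
2021-11-03T18:00,481
2021-11-03T19:00,429
2021-11-03T20:00,246
2021-11-03T21:00,24
2021-11-03T22:00,80
2021-11-03T23:00,96
2021-11-04T06:00,144
2021-11-04T07:00,269
2021-11-04T08:00,597
2021-11-04T09:00,338
2021-11-04T10:00,226
2021-11-04T11:00,559
2021-11-04T12:00,238
2021-11-04T13:00,309
2021-11-04T14:00,651
2021-11-04T15:00,133
2021-11-04T16:00,843
2021-11-04T17:00,1113
2021-11-04T18:00,224
2021-11-04T19:00,568
2021-11-04T20:00,232
2021-11-04T21:00,187
2021-11-04T22:00,111
2021-11-04T23:00,83
2021-11-05T06:00,27
2021-11-05T07:00,209
2021-11-05T08:00,241
2021-11-05T09:00,200
2021-11-05T10:00,115
2021-11-05T11:00,578
2021-11-05T12:00,309
2021-11-05T13:00,303
2021-11-05T14:00,326
2021-11-05T15:00,371
2021-11-05T16:00,833
2021-11-05T17:00,839
2021-11-05T18:00,448
2021-11-05T19:00,102
2021-11-05T20:00,89
2021-11-05T21:00,189
2021-11-05T22:00,128
2021-11-05T23:00,100
2021-11-06T06:00,143
2021-11-06T07:00,190
2021-11-06T08:00,318
2021-11-06T09:00,230
2021-11-06T10:00,217
2021-11-06T11:00,478
2021-11-06T12:00,415
2021-11-06T13:00,311
2021-11-06T14:00,713
2021-11-06T15:00,64
2021-11-06T16:00,354
2021-11-06T17:00,568
2021-11-06T18:00,457
2021-11-06T19:00,212
2021-11-06T20:00,163
2021-11-06T21:00,117
2021-11-06T22:00,111
2021-11-06T23:00,122
2021-11-07T06:00,95
2021-11-07T07:00,156
2021-11-07T08:00,928
2021-11-07T09:00,273
2021-11-07T10:00,225
2021-11-07T11:00,431
2021-11-07T12:00,147
2021-11-07T13:00,39
2021-11-07T14:00,105
2021-11-07T15:00,481
2021-11-07T16:00,1130
2021-11-07T17:00,851
2021-11-07T18:00,377
2021-11-07T19:00,409
2021-11-07T20:00,307
2021-11-07T21:00,138
2021-11-07T22:00,4
2021-11-07T23:00,79
2021-11-08T06:00,120
2021-11-08T07:00,142
2021-11-08T08:00,1099
2021-11-08T09:00,427
2021-11-08T10:00,265
2021-11-08T11:00,191
2021-11-08T12:00,501
2021-11-08T13:00,474
2021-11-08T14:00,357
2021-11-08T15:00,486
2021-11-08T16:00,242
2021-11-08T17:00,1102
2021-11-08T18:00,500
2021-11-08T19:00,417
2021-11-08T20:00,108
2021-11-08T21:00,123
2021-11-08T22:00,206
2021-11-08T23:00,51
2021-11-09T06:00,113
2021-11-09T07:00,296
2021-11-09T08:00,1097
2021-11-09T09:00,314
2021-11-09T10:00,282
2021-11-09T11:00,245
2021-11-09T12:00,429
2021-11-09T13:00,666
2021-11-09T14:00,423
2021-11-09T15:00,456
2021-11-09T16:00,989
2021-11-09T17:00,782
2021-11-09T18:00,198
2021-11-09T19:00,469
2021-11-09T20:00,178
2021-11-09T21:00,118
2021-11-09T22:00,118
2021-11-09T23:00,154
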