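segments:
- kind: baseline
  start_s: 0.0
  end_s: 30.0
- kind: light
  start_s: 30.0
  end_s: 90.0
- kind: dark
  start_s: 90.0
  end_s: 210.0
- kind: light
  start_s: 210.0
  end_s: 240.0
- kind: baseline
  start_s: 240.0
  end_s: 270.0
- kind: acoustic_train
  start_s: 270.0
  end_s: 311.0
  intensity: low
  tap_times_s:
  - 270.0
  - 280.0
  - 290.0
  - 300.0
  - 310.0
- kind: inter_endpoint
  start_s: 311.0
  end_s: 341.0
- kind: acoustic_train
  start_s: 341.0
  end_s: 382.0
  intensity: high
  tap_times_s:
  - 341.0
  - 351.0
  - 361.0
  - 371.0
  - 381.0
- kind: inter_endpoint
  start_s: 382.0
  end_s: 412.0
- kind: baseline
  start_s: 412.0
  end_s: 442.0
- kind: habituation_bout
  start_s: 442.0
  end_s: 502.0
  tap_times_s:
  - 442.0
  - 444.0
  - 446.0
  - 448.0
  - 450.0
  - 452.0
  - 454.0
  - 456.0
  - 458.0
  - 460.0
  - 462.0
  - 464.0
  - 466.0
  - 468.0
  - 470.0
  - 472.0
  - 474.0
  - 476.0
  - 478.0
  - 480.0
  - 482.0
  - 484.0
  - 486.0
  - 488.0
  - 490.0
  - 492.0
  - 494.0
  - 496.0
  - 498.0
  - 500.0
- kind: inter_bout
  start_s: 502.0
  end_s: 522.0
- kind: habituation_bout
  start_s: 522.0
  end_s: 582.0
  tap_times_s:
  - 522.0
  - 524.0
  - 526.0
  - 528.0
  - 530.0
  - 532.0
  - 534.0
  - 536.0
  - 538.0
  - 540.0
  - 542.0
  - 544.0
  - 546.0
  - 548.0
  - 550.0
  - 552.0
  - 554.0
  - 556.0
  - 558.0
  - 560.0
  - 562.0
  - 564.0
  - 566.0
  - 568.0
  - 570.0
  - 572.0
  - 574.0
  - 576.0
  - 578.0
  - 580.0
- kind: inter_bout
  start_s: 582.0
  end_s: 602.0
- kind: habituation_bout
  start_s: 602.0
  end_s: 662.0
  tap_times_s:
  - 602.0
  - 604.0
  - 606.0
  - 608.0
  - 610.0
  - 612.0
  - 614.0
  - 616.0
  - 618.0
  - 620.0
  - 622.0
  - 624.0
  - 626.0
  - 628.0
  - 630.0
  - 632.0
  - 634.0
  - 636.0
  - 638.0
  - 640.0
  - 642.0
  - 644.0
  - 646.0
  - 648.0
  - 650.0
  - 652.0
  - 654.0
  - 656.0
  - 658.0
  - 660.0
- kind: inter_bout
  start_s: 662.0
  end_s: 682.0
- kind: habituation_bout
  start_s: 682.0
  end_s: 742.0
  tap_times_s:
  - 682.0
  - 684.0
  - 686.0
  - 688.0
  - 690.0
  - 692.0
  - 694.0
  - 696.0
  - 698.0
  - 700.0
  - 702.0
  - 704.0
  - 706.0
  - 708.0
  - 710.0
  - 712.0
  - 714.0
  - 716.0
  - 718.0
  - 720.0
  - 722.0
  - 724.0
  - 726.0
  - 728.0
  - 730.0
  - 732.0
  - 734.0
  - 736.0
  - 738.0
  - 740.0
- kind: inter_bout
  start_s: 742.0
  end_s: 762.0
- kind: habituation_bout
  start_s: 762.0
  end_s: 822.0
  tap_times_s:
  - 762.0
  - 764.0
  - 766.0
  - 768.0
  - 770.0
  - 772.0
  - 774.0
  - 776.0
  - 778.0
  - 780.0
  - 782.0
  - 784.0
  - 786.0
  - 788.0
  - 790.0
  - 792.0
  - 794.0
  - 796.0
  - 798.0
  - 800.0
  - 802.0
  - 804.0
  - 806.0
  - 808.0
  - 810.0
  - 812.0
  - 814.0
  - 816.0
  - 818.0
  - 820.0
- kind: inter_endpoint
  start_s: 822.0
  end_s: 852.0
- kind: baseline
  start_s: 852.0
  end_s: 882.0
- kind: acoustic_train
  start_s: 882.0
  end_s: 923.0
  intensity: high
  tap_times_s:
  - 882.0
  - 892.0
  - 902.0
  - 912.0
  - 922.0
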