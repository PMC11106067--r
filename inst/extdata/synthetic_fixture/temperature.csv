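age_ma,temperature_c
       43.6,18.81087786
       43.2,18.63044251
       42.8,18.01926514
       42.4, 18.2045998
         42,18.21459497
       41.6,18.44017438
       41.2,18.50226092
       40.8,18.53903387
       40.4,18.45351923
         40,18.99230897
       39.6,18.49926882
       39.2,18.82687147
       38.8,19.41759836
       38.4,19.15222525
         38,18.89732436
       37.6,19.30485844
       37.2, 19.6205848
       36.8,19.34624666
       36.4,19.77422667
         36,19.34748975
       35.6,19.91551162
       35.2,19.62201212
       34.8,19.75342837
       34.4,20.36148271
         34,20.53546344
       33.6,19.41928875
       33.2,20.37439779
       32.8,20.55273832
       32.4,20.26403441
         32,20.20961006
       31.6,20.70512956
       31.2,21.05363885
       30.8,21.12234583
       30.4, 20.6353116
         30,21.43979975
       29.6,20.50873914
       29.2, 20.6797149
       28.8,21.07098515
       28.4,20.97912949
         28,21.75733233
       27.6,21.64376194
       27.2,21.41580385
       26.8,21.58688373
       26.4, 21.8091256
         26,21.57487938
       25.6,21.13503181
       25.2,21.92288214
       24.8,21.70780794
       24.4,20.96088046
         24,21.73310205
       23.6,20.64663352
       23.2,20.57999132
       22.8,19.93453151
       22.4,19.41561459
         22,19.55347955
       21.6,19.12818166
       21.2,19.52712407
       20.8, 19.3297518
       20.4,18.24622026
         20,18.59078892
       19.6,17.73502645
       19.2,17.18822247
       18.8,17.49739758
       18.4,17.41941038
         18,17.03498227
       17.6,16.30297791
       17.2,15.89358684
       16.8,15.49969101
       16.4,15.61656437
         16,14.03799374
       15.6,14.20132493
       15.2,13.88947348
       14.8, 13.7216252
       14.4,12.96949176
         14,12.33697663
       13.6,11.97885861
       13.2,12.78547253
       12.8,12.59870018
       12.4,12.72077535
         12,10.97216266
       11.6,11.17538476
       11.2,10.87182696
       10.8,11.21100979
       10.4,10.53517361
         10,11.49953292
        9.6,10.64158565
        9.2,10.77824423
        8.8, 10.7525872
        8.4,11.21028907
          8,9.962120553
        7.6,10.85237691
        7.2,10.32032822
        6.8,10.13360625
        6.4, 10.2784944
          6, 10.2885899
        5.6,9.677909533
        5.2,9.742711173
        4.8,9.056902149
        4.4,9.386670183
          4,8.718365862
        3.6,9.525341516
        3.2, 8.59598665
        2.8,9.355845246
        2.4,8.750414203
          2,7.945391099
        1.6,8.142923966
        1.2,7.943251039
        0.8,7.792222968
        0.4,7.993334263
          0,7.367862867
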