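samples:
- id: S001
  spikes:
  - change: T315I
    vaf: 17.76
  - change: F359V
    vaf: 63.43
- id: S004
  spikes:
  - change: G250E
    vaf: 52.01
  - change: M244V
    vaf: 5.01
  - change: E255V
    vaf: 3.14
- id: S016
  spikes:
  - change: F359C
    vaf: 34.67
  - change: F317L
    vaf: 11.83
  - change: E255V
    vaf: 11.4
  - change: G250E
    vaf: 4.08
- id: S017
  spikes:
  - change: T315I
    vaf: 31.17
  - change: G250E
    vaf: 57.24
- id: S002
  spikes:
  - change: T315I
    vaf: 44.45
  - change: F317L
    vaf: 11.29
  - change: L248V
    vaf: 18.56
  - change: E255K
    vaf: 17.04
- id: S003
  spikes:
  - change: T315I
    vaf: 43.28
  - change: F317L
    vaf: 2.52
  - change: L248V
    vaf: 2.59
  - change: M351T
    vaf: 3.65
- id: S005
  spikes:
  - change: T315I
    vaf: 52.51
  - change: G250E
    vaf: 5.65
  - change: M244V
    vaf: 8.38
  - change: E459K
    vaf: 9.99
- id: S006
  spikes:
  - change: F317L
    vaf: 56.06
  - change: L248V
    vaf: 8.29
  - change: F359V
    vaf: 2.73
  - change: E255V
    vaf: 15.72
- id: S007
  spikes:
  - change: T315I
    vaf: 61.45
  - change: L248V
    vaf: 7.25
  - change: E355G
    vaf: 8.04
- id: S008
  spikes:
  - change: M351T
    vaf: 50.66
- id: S009
  spikes:
  - change: L248V
    vaf: 52.14
- id: S010
  spikes:
  - change: Y253F
    vaf: 19.39
- id: S011
  spikes:
  - change: T315I
    vaf: 2.3
- id: S012
  spikes:
  - change: F317L
    vaf: 75.7
- id: S013
  spikes:
  - change: T315I
    vaf: 93.41
- id: S014
  spikes:
  - change: T315I
    vaf: 60.92
- id: S015
  spikes:
  - change: F317L
    vaf: 75.4
- id: S018
  spikes:
  - change: L248V
    vaf: 26.31
- id: S019
  spikes:
  - change: T315I
    vaf: 52.44
- id: S020
  spikes:
  - change: Y253H
    vaf: 67.23
- id: S021
  spikes:
  - change: T315I
    vaf: 13.86
- id: S022
  spikes:
  - change: F359V
    vaf: 28.83
- id: S023
  spikes:
  - change: F317L
    vaf: 8.34
- id: S024
  spikes:
  - change: T315I
    vaf: 35.37
- id: S025
  spikes:
  - change: F317L
    vaf: 39.99
- id: S026
  spikes:
  - change: M244V
    vaf: 90.81
- id: S027
  spikes:
  - change: F359V
    vaf: 15.07
- id: S028
  spikes:
  - change: G250E
    vaf: 60.28
- id: S029
  spikes:
  - change: G250E
    vaf: 62.92
- id: S030
  spikes:
  - change: T315I
    vaf: 52.12
- id: S031
  spikes:
  - change: L387M
    vaf: 11.77
- id: S032
  spikes:
  - change: H396R
    vaf: 16.29
- id: S033
  spikes:
  - change: M351T
    vaf: 59.75
- id: S034
  spikes:
  - change: M244V
    vaf: 27.79
- id: S035
  spikes:
  - change: E255K
    vaf: 55.33
- id: S036
  spikes:
  - change: T315I
    vaf: 55.24
- id: S037
  spikes:
  - change: F317L
    vaf: 40.47
- id: S038
  spikes:
  - change: F317L
    vaf: 71.77
- id: S039
  spikes:
  - change: L248V
    vaf: 81.95
- id: S040
  spikes:
  - change: E255K
    vaf: 29.21
- id: S041
  spikes:
  - change: L248V
    vaf: 4.03
- id: S042
  spikes:
  - change: H396P
    vaf: 48.46
- id: S043
  spikes: []
- id: S044
  spikes: []
- id: S045
  spikes: []
- id: S046
  spikes: []
- id: S047
  spikes: []
- id: S048
  spikes: []
- id: S049
  spikes: []
- id: S050
  spikes: []
- id: S051
  spikes: []
- id: S052
  spikes: []
- id: S053
  spikes: []
- id: S054
  spikes: []
- id: S055
  spikes: []
- id: S056
  spikes: []
- id: S057
  spikes: []
- id: S058
  spikes: []
- id: S059
  spikes: []
- id: S060
  spikes: []
- id: S061
  spikes: []
- id: S062
  spikes: []
- id: S063
  spikes: []
- id: S064
  spikes: []
- id: S065
  spikes: []
- id: S066
  spikes: []
- id: S067
  spikes: []
- id: S068
  spikes: []
- id: S069
  spikes: []
- id: S070
  spikes: []
- id: S071
  spikes: []
- id: S072
  spikes: []
- id: S073
  spikes: []
- id: S074
  spikes: []
- id: S075
  spikes: []
- id: S076
  spikes: []
- id: S077
  spikes: []
- id: S078
  spikes: []
- id: S079
  spikes: []
- id: S080
  spikes: []
- id: S081
  spikes: []
- id: S082
  spikes: []
- id: S083
  spikes: []
- id: S084
  spikes: []
- id: S085
  spikes: []
- id: S086
  spikes: []
- id: S087
  spikes: []
- id: S088
  spikes: []
- id: S089
  spikes: []
- id: S090
  spikes: []
- id: S091
  spikes: []
- id: S092
  spikes: []
- id: S093
  spikes: []
- id: S094
  spikes: []
- id: S095
  spikes: []
- id: S096
  spikes: []
- id: S097
  spikes: []
- id: S098
  spikes: []
- id: S099
  spikes: []
- id: S100
  spikes: []
- id: S101
  spikes: []
- id: S102
  spikes: []
- id: S103
  spikes: []
- id: S104
  spikes: []
- id: S105
  spikes: []
- id: S106
  spikes: []
- id: S107
  spikes: []
- id: S108
  spikes: []
- id: S109
  spikes: []
- id: S110
  spikes: []
- id: S111
  spikes: []
- id: S112
  spikes: []
- id: S113
  spikes: []
- id: S114
  spikes: []
- id: S115
  spikes: []
- id: S116
  spikes: []
- id: S117
  spikes: []
- id: S118
  spikes: []
- id: S119
  spikes: []
- id: S120
  spikes: []
- id: S121
  spikes: []
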