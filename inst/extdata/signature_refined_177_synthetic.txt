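# Synthetic stand-in for the refined epithelial-specific signature (177 placeholder symbols).
# These are NOT published gene identities; they mirror the published list size only.
MSG0001
MSG0002
MSG0003
MSG0004
MSG0005
MSG0006
MSG0007
MSG0008
MSG0009
MSG0010
MSG0011
MSG0012
MSG0013
MSG0014
MSG0015
MSG0016
MSG0017
MSG0018
MSG0019
MSG0020
MSG0021
MSG0022
MSG0023
MSG0024
MSG0025
MSG0026
MSG0027
MSG0028
MSG0029
MSG0030
MSG0031
MSG0032
MSG0033
MSG0034
MSG0035
MSG0036
MSG0037
MSG0038
MSG0039
MSG0040
MSG0041
MSG0042
MSG0043
MSG0044
MSG0045
MSG0046
MSG0047
MSG0048
MSG0049
MSG0050
MSG0051
MSG0052
MSG0053
MSG0054
MSG0055
MSG0056
MSG0057
MSG0058
MSG0059
MSG0060
MSG0061
MSG0062
MSG0063
MSG0064
MSG0065
MSG0066
MSG0067
MSG0068
MSG0069
MSG0070
MSG0071
MSG0072
MSG0073
MSG0074
MSG0075
MSG0076
MSG0077
MSG0078
MSG0079
MSG0080
MSG0081
MSG0082
MSG0083
MSG0084
MSG0085
MSG0086
MSG0087
MSG0088
MSG0089
MSG0090
MSG0091
MSG0092
MSG0093
MSG0094
MSG0095
MSG0096
MSG0097
MSG0098
MSG0099
MSG0100
MSG0101
MSG0102
MSG0103
MSG0104
MSG0105
MSG0106
MSG0107
MSG0108
MSG0109
MSG0110
MSG0111
MSG0112
MSG0113
MSG0114
MSG0115
MSG0116
MSG0117
MSG0118
MSG0119
MSG0120
MSG0121
MSG0122
MSG0123
MSG0124
MSG0125
MSG0126
MSG0127
MSG0128
MSG0129
MSG0130
MSG0131
MSG0132
MSG0133
MSG0134
MSG0135
MSG0136
MSG0137
MSG0138
MSG0139
MSG0140
MSG0141
MSG0142
MSG0143
MSG0144
MSG0145
MSG0146
MSG0147
MSG0148
MSG0149
MSG0150
MSG0151
MSG0152
MSG0153
MSG0154
MSG0155
MSG0156
MSG0157
MSG0158
MSG0159
MSG0160
MSG0161
MSG0162
MSG0163
MSG0164
MSG0165
MSG0166
MSG0167
MSG0168
MSG0169
MSG0170
MSG0171
MSG0172
MSG0173
MSG0174
MSG0175
MSG0176
MSG0177
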