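symbol
ANK2
INTS1
XIRP1
USP34
CAND005
CAND006
CAND007
CAND008
CAND009
CAND010
CAND011
CAND012
CAND013
CAND014
CAND015
CAND016
CAND017
CAND018
CAND019
CAND020
CAND021
CAND022
CAND023
CAND024
CAND025
CAND026
CAND027
CAND028
CAND029
CAND030
CAND031
CAND032
CAND033
CAND034
CAND035
CAND036
CAND037
CAND038
CAND039
CAND040
CAND041
CAND042
CAND043
CAND044
CAND045
CAND046
CAND047
CAND048
CAND049
CAND050
CAND051
CAND052
CAND053
CAND054
CAND055
CAND056
CAND057
CAND058
CAND059
CAND060
CAND061
CAND062
CAND063
CAND064
CAND065
CAND066
CAND067
CAND068
CAND069
CAND070
CAND071
CAND072
CAND073
CAND074
CAND075
CAND076
CAND077
CAND078
CAND079
CAND080
CAND081
CAND082
CAND083
CAND084
CAND085
CAND086
CAND087
CAND088
CAND089
CAND090
CAND091
CAND092
CAND093
CAND094
CAND095
CAND096
CAND097
CAND098
CAND099
CAND100
CAND101
CAND102
CAND103
CAND104
CAND105
CAND106
CAND107
CAND108
CAND109
CAND110
CAND111
CAND112
CAND113
CAND114
CAND115
CAND116
CAND117
CAND118
CAND119
CAND120
CAND121
CAND122
CAND123
CAND124
CAND125
CAND126
CAND127
CAND128
CAND129
CAND130
CAND131
CAND132
CAND133
CAND134
CAND135
CAND136
CAND137
CAND138
CAND139
CAND140
CAND141
CAND142
CAND143
CAND144
CAND145
CAND146
CAND147
CAND148
CAND149
CAND150
CAND151
CAND152
CAND153
CAND154
CAND155
CAND156
CAND157
CAND158
CAND159
CAND160
CAND161
CAND162
CAND163
CAND164
CAND165
CAND166
CAND167
CAND168
CAND169
CAND170
CAND171
CAND172
CAND173
CAND174
CAND175
CAND176
CAND177
CAND178
CAND179
CAND180
CAND181
CAND182
CAND183
CAND184
CAND185
CAND186
CAND187
CAND188
CAND189
CAND190
CAND191
CAND192
CAND193
CAND194
CAND195
CAND196
CAND197
CAND198
CAND199
CAND200
CAND201
CAND202
CAND203
CAND204
CAND205
CAND206
CAND207
CAND208
CAND209
CAND210
CAND211
CAND212
CAND213
CAND214
CAND215
CAND216
CAND217
CAND218
CAND219
CAND220
CAND221
CAND222
CAND223
CAND224
CAND225
CAND226
CAND227
CAND228
CAND229
CAND230
CAND231
CAND232
CAND233
CAND234
CAND235
CAND236
CAND237
CAND238
CAND239
CAND240
CAND241
CAND242
CAND243
CAND244
CAND245
CAND246
CAND247
CAND248
CAND249
CAND250
CAND251
CAND252
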