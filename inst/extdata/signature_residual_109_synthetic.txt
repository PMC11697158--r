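# Synthetic stand-in for the residual microenvironment signature (109 placeholder symbols).
# These are NOT published gene identities; they mirror the published list size only.
MSG0178
MSG0179
MSG0180
MSG0181
MSG0182
MSG0183
MSG0184
MSG0185
MSG0186
MSG0187
MSG0188
MSG0189
MSG0190
MSG0191
MSG0192
MSG0193
MSG0194
MSG0195
MSG0196
MSG0197
MSG0198
MSG0199
MSG0200
MSG0201
MSG0202
MSG0203
MSG0204
MSG0205
MSG0206
MSG0207
MSG0208
MSG0209
MSG0210
MSG0211
MSG0212
MSG0213
MSG0214
MSG0215
MSG0216
MSG0217
MSG0218
MSG0219
MSG0220
MSG0221
MSG0222
MSG0223
MSG0224
MSG0225
MSG0226
MSG0227
MSG0228
MSG0229
MSG0230
MSG0231
MSG0232
MSG0233
MSG0234
MSG0235
MSG0236
MSG0237
MSG0238
MSG0239
MSG0240
MSG0241
MSG0242
MSG0243
MSG0244
MSG0245
MSG0246
MSG0247
MSG0248
MSG0249
MSG0250
MSG0251
MSG0252
MSG0253
MSG0254
MSG0255
MSG0256
MSG0257
MSG0258
MSG0259
MSG0260
MSG0261
MSG0262
MSG0263
MSG0264
MSG0265
MSG0266
MSG0267
MSG0268
MSG0269
MSG0270
MSG0271
MSG0272
MSG0273
MSG0274
MSG0275
MSG0276
MSG0277
MSG0278
MSG0279
MSG0280
MSG0281
MSG0282
MSG0283
MSG0284
MSG0285
MSG0286
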