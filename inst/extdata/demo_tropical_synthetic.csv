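sig001,sig002,sig003,sig004,sig005,sig006,sig007,sig008,sig009,sig010,sig011,sig012,noise0001,noise0002,noise0003,noise0004,noise0005,noise0006,noise0007,noise0008,noise0009,noise0010,noise0011,noise0012,noise0013,noise0014,noise0015,noise0016,noise0017,noise0018,noise0019,noise0020,noise0021,noise0022,noise0023,noise0024,label
-0.57707,0.33371,1.29088,0.28293,-0.6454,-0.94325,0.30764,-0.9075,0.26974,1.26789,0.2293,-0.79081,-0.00058,-0.01509,-0.00246,0.00189,-0.00341,-0.00905,-0.00497,-0.01735,0.01326,-0.0035,0.0012,-0.00745,0.00582,-0.00852,0.0045,0.01599,0.0141,0.01197,0.00142,0.01364,0.0099,-0.00885,0.00706,0.01674,1
-1.07563,0.83954,1.0466,1.04205,-1.22665,-0.80513,0.54998,-0.87691,1.00018,1.26559,0.53616,-1.1279,0.00449,-0.01138,-0.00354,0.00691,-0.00131,-0.00316,-0.00322,0.01637,0.01297,-0.00189,-0.00247,0.00179,-0.00449,0.00934,-0.00244,-0.02009,0.0052,-0.00075,0.00416,-0.00525,-0.01928,-0.01509,0.00639,0.00523,1
0.68886,-0.37796,-1.28071,-0.52634,0.72724,-0.38974,-0.73767,-0.57084,-0.46623,-1.35059,-0.66364,0.60632,0.01077,0.00338,0.00268,0.00822,0.01647,-0.0115,-0.01679,0.00463,-0.00389,0.00488,0.01032,0.0024,-0.00438,-0.00074,-0.00386,-0.00718,-0.00571,0.00645,-0.01068,-0.02188,-0.00598,0.00134,-0.02044,0.01933,0
-0.11429,-0.40752,-1.26073,-0.31324,0.10263,0.23145,0.63112,0.24505,-0.27384,-1.22198,0.59271,0.0261,0.00186,-0.01473,0.00454,-0.00976,0.01556,-0.01875,0.01331,-0.01689,0.00808,0.01113,0.00392,-0.00382,0.00205,-0.00162,-0.00544,0.0042,-0.00198,-0.00237,0.00545,0.03197,-0.01289,-0.0066,-0.0115,0.0025,0
0.05204,0.95985,0.7688,1.05497,0.05147,-1.04201,0.25781,-0.90849,0.80228,0.56179,0.22278,0.10237,0.01569,-0.00292,-0.02688,-0.01295,-0.01327,0.00821,-0.00952,-0.0128,0.00768,-0.02225,-0.00488,0.00565,0.00043,-0.01579,-0.00105,-0.01197,-0.02593,0.00147,0.02361,0.00577,-0.0011,0.00606,-0.01517,0.00748,1
-1.07317,0.55338,-0.57388,0.44884,-0.9855,-0.59154,-0.59736,-0.45554,0.50766,-0.5573,-0.5481,-0.87545,-0.00227,-0.0203,0.00867,0.00863,-0.0043,-0.00718,-0.01068,0.0188,-0.00105,0.01931,0.0095,-0.00142,-0.00139,-0.01046,-0.01609,0.00324,-0.01197,0.02898,0.00123,-0.00275,0.00295,0.00218,-0.00369,0.01001,1
1.79544,-0.1902,-1.58748,-0.17632,1.98213,0.90698,-0.6766,0.76377,-0.42084,-1.5926,-0.65707,1.75491,0.00766,-0.00594,0.00169,-0.00128,0.00814,-0.01146,0.00112,0.00597,0.00643,0.02553,-0.01089,0.0045,0.01414,0.00469,0.01001,-0.0072,-0.01276,-0.00884,-0.00285,0.02324,-0.01401,-0.00817,0.0184,-0.00078,0
-0.07687,-0.8042,0.87877,-0.67998,-0.09185,0.93046,-0.15197,0.78761,-0.74277,0.71614,-0.00722,-0.12241,-0.00312,-0.01055,-0.01091,-0.00329,0.00035,0.01187,0.00347,-0.01963,-0.0253,-0.0116,0.00194,0.00618,0.00725,-0.0019,-0.0011,-0.00504,-0.0067,0.00655,0.02693,0.0199,0.00819,-0.00499,0.00333,0.02119,1
-0.67711,-0.33765,1.27048,-0.28867,-0.4642,0.38608,0.47432,0.54442,-0.4138,1.05744,0.56689,-0.56179,-0.01355,-0.01078,-0.0038,0.01369,-0.00398,-0.01295,-0.01366,0.00084,0.00243,-0.00709,-0.01908,-0.00379,0.00987,-0.00702,0.00758,-0.00744,0.0167,0.02851,0.00771,0.0048,0.00838,0.00048,-0.01265,0.00726,1
1.86784,-0.2709,-1.61296,-0.39954,1.74778,-0.23702,0.56394,-0.38192,-0.41897,-1.53328,0.352,1.84704,-0.00906,0.01281,-0.00948,-0.01474,-0.00292,0.01073,-0.00394,-0.01693,-0.01596,0.00793,0.00696,-0.00346,-0.00195,-0.01482,0.02159,0.00986,-0.00242,-0.00232,0.00431,-0.01603,0.01101,-0.00758,0.00438,0.01256,0
-0.5362,0.07391,0.31268,0.09509,-0.69673,-0.10499,0.60725,-0.00977,0.01274,0.32485,0.59846,-0.71455,-0.00651,0.00081,0.00721,0.00504,0.00578,-0.01092,0.00316,-0.01841,0.00076,-0.00078,0.00059,-0.00641,-0.00772,0.0212,-0.0091,-0.00099,0.00446,0.01714,0.01608,-0.00395,-0.01305,-0.00866,-0.00343,0.0033,1
0.67863,-0.4694,-1.09385,-0.25902,0.40297,0.50395,-0.48969,0.42839,-0.41363,-1.1437,-0.51794,0.53579,-0.01045,-0.00993,-0.00159,-0.01788,-0.01475,-0.01563,-0.00849,0.00066,0.0159,0.01295,-3e-04,0.00402,0.01459,0.01135,0.0113,-0.00439,-0.00537,-0.01174,0.0165,0.00313,-0.00557,0.01481,0.00139,0.01292,0
-1.21851,0.54346,0.67917,0.73362,-1.01158,0.34699,0.65233,0.26094,0.60219,0.81856,0.99546,-1.08962,0.01594,-0.00757,-0.01788,-0.02272,-0.0022,-0.02436,0.01006,0.00012,0.00527,0.00499,-0.01279,0.00335,0.00409,-0.00863,0.01367,0.00744,0.00628,0.0045,-0.01354,-0.00916,0.00901,-0.0036,0.00125,-3e-05,1
0.76615,-0.99036,-0.94172,-0.72191,0.5353,0.12698,-0.18553,0.40538,-0.68337,-0.89514,-0.32717,0.71144,0.00542,9e-05,0.01494,0.01598,0.00636,-0.01532,-0.02275,-0.0136,-0.007,-0.01311,-0.00247,0.00068,-0.00692,-0.00612,0.00869,0.02445,0.00894,-0.01049,0.00697,-0.00959,0.0042,0.01114,-0.01533,0.00775,0
-0.1963,0.04132,0.53471,-0.33669,-0.22352,-0.58663,-0.64994,-0.67692,-0.10138,0.24164,-0.7082,-0.27027,-0.02366,0.01409,0.01524,-0.00692,0.00304,0.00099,-0.00822,0.00161,-0.00443,0.00443,0.01659,-0.00612,0.00037,0.00208,0.00455,0.00043,0.01233,-0.01481,-0.0051,-0.00769,-0.00745,0.00182,0.01267,0.00567,1
-1.82557,0.34602,1.27694,0.19793,-1.81784,-0.54299,0.63148,-0.51435,-0.07571,1.35756,0.3956,-1.87428,0.00471,0.00293,0.00459,-0.01187,0.0085,-0.0201,0.0049,0.00447,-0.01233,-0.0121,0.00951,0.00543,-0.00619,-7e-04,0.01725,0.00159,0.00521,-0.0086,-0.00459,-0.02684,-0.00034,0.00525,0.00934,0.01235,1
-0.27124,-0.8121,1.25053,-0.80714,-0.44887,-0.19035,-0.21156,-0.07845,-0.7322,1.48505,-0.26136,-0.35658,-0.00232,0.00297,-0.00812,-0.00447,0.00466,0.00583,0.00928,-0.01455,-0.02363,-0.00134,0.00836,-0.01106,0.00145,0.0123,-0.00459,0.01686,0.0199,-0.01047,-0.00776,0.01532,0.00888,-0.00981,-0.00425,0.00465,1
1.14404,0.38326,-1.93797,0.31022,1.30734,0.7673,0.6381,0.8254,0.20051,-1.73381,0.54383,1.23726,0.00094,-0.01403,0.01055,0.01344,0.00421,0.00885,7e-04,0.00363,0.00858,-0.00171,0.00689,-0.00361,0.01084,0.00053,-0.007,0.00193,-0.00952,-0.00441,-0.02408,0.00922,-0.01392,-2e-05,-0.01484,0.00179,0
-1.66644,-0.55975,1.04435,-0.54424,-1.36616,0.73221,-0.26168,0.85388,-0.43601,0.92786,-0.30923,-1.58902,-0.01295,0.00104,-0.00908,0.007,0.009,0.00163,-0.00562,-0.00275,0.01508,-0.00906,0.0068,-0.00343,-0.00478,0.00067,0.00235,-0.00883,0.00626,-0.00879,0.00811,-0.01187,0.00249,-0.00119,-0.01601,-0.00539,1
0.3033,-0.08187,-0.43803,-0.22082,0.24744,0.42515,0.4057,0.5202,0.08865,-0.45173,0.31011,0.46271,-0.00849,0.00371,-0.00417,0.00203,0.01287,-0.0086,0.01269,0.01143,0.00028,0.01388,-0.01576,0.02227,0.00117,-0.02961,0.00275,-0.00133,0.00733,-0.00012,-0.00865,-0.00204,-0.01664,-0.01425,0.00927,-0.00958,0
-0.75694,0.39203,0.60629,0.45,-0.85317,0.48253,0.54479,0.3383,0.55898,0.63391,0.5327,-0.88554,-0.0229,-0.01676,0.01128,-0.0111,-0.00874,0.00975,-0.01631,-0.00365,-0.00992,8e-05,-0.01733,-0.01414,0.00472,-0.00131,0.0118,0.00404,-0.00582,0.00685,0.013,-0.01059,-0.01355,-0.00487,0.009,-0.01202,1
1.25806,0.9122,-0.92732,0.57246,1.13896,0.23325,-0.72904,0.08216,0.77719,-1.05955,-0.49449,1.22784,0.01283,0.01785,0.00934,0.02095,-0.0083,-0.00619,0.00511,0.00658,-0.00167,0.00432,-0.00526,0.0125,-0.00558,-0.01643,0.01107,0.00609,0.00983,-0.00923,0.00594,0.00661,0.01025,-0.00267,-0.00668,0.00861,0
1.8538,0.24352,-0.52617,0.28963,1.82511,-0.86926,-0.88476,-1.07217,0.60405,-0.32174,-0.75913,1.9896,0.01664,-0.02277,0.00446,-0.01148,-0.00135,-0.00527,-0.00693,-0.01236,-0.00131,0.0207,0.01429,0.01146,-0.01691,-0.00459,0.00173,-0.01062,0.00428,0.00092,-0.01997,-0.00333,-0.01391,0.00233,0.00478,-0.01339,0
-0.34286,-0.32028,1.22059,-0.20384,-0.2369,0.22958,-0.68867,0.39735,-0.24543,1.20315,-0.62247,-0.24318,0.00401,-0.0159,-0.00059,0.01072,0.00193,-0.01757,0.00306,0.00817,-0.00696,-0.00299,0.00576,-0.00057,-0.00208,-0.008,-0.00274,0.01696,0.0045,-0.02035,-0.00925,0.01264,-0.0172,-0.00406,0.00448,0.00624,1
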