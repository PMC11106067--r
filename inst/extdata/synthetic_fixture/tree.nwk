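((((t13:6.779977602,(t5:6.319337794,(t11:3.576652792,(t15:2.166461541,t2:2.166461541):1.410191251):2.742685002):0.4606398082):1.361537724,(t4:7.262755537,t1:7.262755537):0.8787597887):29.26696953,(t3:5.629700448,t9:5.629700448):31.77878441):4.35246038,(((t16:13.63275713,((t6:3.125572872,t8:3.125572872):3.468916532,(t10:0.6023037413,t12:0.6023037413):5.992185663):7.038267721):3.779926621,t7:17.41268375):1.731159483,t14:19.14384323):22.61710201);
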