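(((sp004:0.05305835174,(sp010:0.0005615273602,sp011:0.0005615273602):0.05249682438):0.8469133606,((sp012:0.4494195571,(sp008:0.4000858244,((sp009:0.1626257004,sp007:0.1626257004):0.06574555668,(sp006:0.03772160206,sp001:0.03772160206):0.190649655):0.1717145673):0.04933373276):0.3377740328,(sp002:0.04169548916,sp005:0.04169548916):0.7454981008):0.1127781225):0.1000282876,sp003:1);
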