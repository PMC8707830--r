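module,member,expected_direction,legible
ornithine-asparagine-polyamine,ornithine,consumption,TRUE
ornithine-asparagine-polyamine,L-asparagine,consumption,TRUE
ornithine-asparagine-polyamine,Asn + 2hexoside,consumption,TRUE
ornithine-asparagine-polyamine,putrescine,accumulation,TRUE
ornithine-asparagine-polyamine,spermidine,accumulation,TRUE
ornithine-asparagine-polyamine,agmatine,accumulation,TRUE
ornithine-asparagine-polyamine,N-acetylspermine,special,TRUE
ornithine-asparagine-polyamine,polyamine derivative 1 (unresolved),accumulation,FALSE
ornithine-asparagine-polyamine,polyamine derivative 2 (unresolved),accumulation,FALSE
ornithine-asparagine-polyamine,polyamine derivative 3 (unresolved),accumulation,FALSE
ornithine-asparagine-polyamine,polyamine derivative 4 (unresolved),accumulation,FALSE
ornithine-asparagine-polyamine,polyamine derivative 5 (unresolved),accumulation,FALSE
ornithine-asparagine-polyamine,polyamine derivative 6 (unresolved),accumulation,FALSE
ornithine-asparagine-polyamine,polyamine derivative 7 (unresolved),accumulation,FALSE
ornithine-asparagine-polyamine,polyamine derivative 8 (unresolved),accumulation,FALSE
shikimate-aromatic-flavonoid,shikimic acid,accumulation,TRUE
shikimate-aromatic-flavonoid,L-tyrosine,accumulation,TRUE
shikimate-aromatic-flavonoid,L-phenylalanine,accumulation,TRUE
shikimate-aromatic-flavonoid,tryptamine,accumulation,TRUE
shikimate-aromatic-flavonoid,N-benzoyltryptamine,accumulation,TRUE
shikimate-aromatic-flavonoid,N-feruloyltryptamine,accumulation,TRUE
shikimate-aromatic-flavonoid,kynurenine,accumulation,TRUE
shikimate-aromatic-flavonoid,"cyanidin 3,5-di-O-hexoside",consumption,TRUE
shikimate-aromatic-flavonoid,epicatechin O-hexoside derivative,accumulation,TRUE
shikimate-aromatic-flavonoid,Methylisohaenkeanoside,accumulation,TRUE
shikimate-aromatic-flavonoid,flavonoid member 1 (unresolved),accumulation,FALSE
shikimate-aromatic-flavonoid,flavonoid member 2 (unresolved),accumulation,FALSE
shikimate-aromatic-flavonoid,flavonoid member 3 (unresolved),accumulation,FALSE
shikimate-aromatic-flavonoid,flavonoid member 4 (unresolved),accumulation,FALSE
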