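# 20 fixed-structure free-energy fixtures; reference values computed once
# with a reference folding program constrained to the same structure
# (RNAeval -d0, Turner 2004) and frozen.
energy_fixture_cases <- list(
  list(seq = "AUGAUGCGCCGGGCCGAAAAACACGGAAGACGGCCCGGCGCCAAGU",
       db  = ".....(((((((((((..............))))))))))).....", ref = -24.80),
  list(seq = "AUGAUGCGCCCCGCGCGGAAAAAAUCCUCGGCUUGUUGCCGAGGUUCCGCGCGGGGCGCGGAGA",
       db  = ".....((((((((((((((......(((((((.....))))))).)))))))))))))).....", ref = -46.30),
  list(seq = "CCAUCCCGCUGAAGUCCAAAAAGUGUAUUGAAGGCAGGACAAGCGGGAUGG",
       db  = "((((((((((...((((...................)))).))))))))))", ref = -22.60),
  list(seq = "GUGAUCCGCGCGAAAAAAACUUCCGCGCGGGGAAC",
       db  = ".....(((((((...........))))))).....", ref = -12.20),
  list(seq = "GUGAUGGGCUCCCGGCACCAAAAACGGUGUGGGCACCUGUGGGGUGCCGGGAGCCCUGACC",
       db  = ".....((((((((((((((......((((....)))).....)))))))))))))).....", ref = -38.50),
  list(seq = "ACACAGCGCGGAACCGAAAAAAAAAUCCAUCGGACGCGCUGUGU",
       db  = "((((((((((...(((..............))).))))))))))", ref = -19.80),
  list(seq = "GUGAACCACGGCGGCCGAAAAAAGAGACCCGGCCGCCGUGGCAAAG",
       db  = ".....((((((((((((............)))))))))))).....", ref = -26.30),
  list(seq = "GUGAACGUCCGGCCGCGGAAAAAGCCGCCGCGCUUACGGCGGCCCCGCGGCCGGACGCAAGG",
       db  = ".....(((((((((((((.....(((((((......))))))).))))))))))))).....", ref = -43.70),
  list(seq = "GCGGAACAGCAAAAACCCUUCCAUGAUUUGCUGACGC",
       db  = "(((...((((...................)))).)))", ref = -5.40),
  list(seq = "AUGACCCGGCCCAAAAAAGAAGUGGGCCGGUGACU",
       db  = ".....((((((((.........)))))))).....", ref = -15.00),
  list(seq = "AUGAGCGGGCGGGAAAAAGGGCCCGGAUAUCGCCGGGCCCUGAGGCCCCGCCCGCGAAC",
       db  = ".....((((((((.....((((((((......))))))))......)))))))).....", ref = -36.40),
  list(seq = "AGACUCGCGGAAGCGCAAAAAUGAAGCUUGGCGGGCGCACGCGAGUCU",
       db  = "(((((((((...((((..................)))).)))))))))", ref = -20.10),
  list(seq = "GUGAGCGGCGCGGAAAAAGUAUAUGACUCCGCGCCGAAAGA",
       db  = ".....((((((((...............)))))))).....", ref = -15.20),
  list(seq = "GUGAGGACGCGAAUGCGCAAAAACCGGGGGUCUACCCCCGGAAUAGGGCGCAUUCGCGUCCAAGU",
       db  = ".....(((((((((((((.....(((((((....)))))))......))))))))))))).....", ref = -40.50),
  list(seq = "GCCGGUAGAACCAGGCAAAAAUCUAGGCCUGGAUACCGGC",
       db  = "(((((((...((((((..........)))))).)))))))", ref = -22.00),
  list(seq = "GUGAAGGGCGUGGGGGGUGGAAAAAUAACGGGCAGCAACCCACCCCCCACGCCCGAACU",
       db  = ".....(((((((((((((((...................))))))))))))))).....", ref = -35.10),
  list(seq = "GUGAUCCCGGCGCAAAAUCGAGCGAUCCGCUCGAUGUCACGCGCCGGGCGAGG",
       db  = ".....((((((((....(((((((...)))))))......)))))))).....", ref = -26.80),
  list(seq = "CGCACCGAAGAGAAAAACUCAGGUGCG",
       db  = "((((((...(((.....))).))))))", ref = -11.00),
  list(seq = "GGGCGCAAAAAAAGCGCCC",
       db  = "((((((.......))))))", ref = -11.30),
  list(seq = "GUGUCGAAUGCAAAAACAUGUUAGGCAAGACAC",
       db  = "(((((...(((.............))).)))))", ref = -6.00)
)
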