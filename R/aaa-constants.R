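# package-wide constants (file collates first)

DNA_BASES <- c("A", "C", "G", "T")

# chemical-property indicators: ring count (a: purine), hydrogen bonding
# (b: weak/A-T), functional group (c: amino/A-C)
NCP_TABLE <- matrix(
  c(1, 1, 1,   # A
    0, 0, 1,   # C
    1, 0, 0,   # G
    0, 1, 0),  # T
  nrow = 4, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T"), c("a", "b", "c"))
)
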