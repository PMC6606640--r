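# The published BLOSUM62 substitution matrix (Henikoff & Henikoff) restricted
# to the 20 canonical amino acids, in the standard NCBI residue order.
# A plain-text copy ships in inst/extdata/BLOSUM62.txt for checksum tests.

AA_CANONICAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

BLOSUM62_MATRIX <- matrix(c(
   4L, -1L, -2L, -2L,  0L, -1L, -1L,  0L, -2L, -1L, -1L, -1L, -1L, -2L, -1L,  1L,  0L, -3L, -2L,  0L,
  -1L,  5L,  0L, -2L, -3L,  1L,  0L, -2L,  0L, -3L, -2L,  2L, -1L, -3L, -2L, -1L, -1L, -3L, -2L, -3L,
  -2L,  0L,  6L,  1L, -3L,  0L,  0L,  0L,  1L, -3L, -3L,  0L, -2L, -3L, -2L,  1L,  0L, -4L, -2L, -3L,
  -2L, -2L,  1L,  6L, -3L,  0L,  2L, -1L, -1L, -3L, -4L, -1L, -3L, -3L, -1L,  0L, -1L, -4L, -3L, -3L,
   0L, -3L, -3L, -3L,  9L, -3L, -4L, -3L, -3L, -1L, -1L, -3L, -1L, -2L, -3L, -1L, -1L, -2L, -2L, -1L,
  -1L,  1L,  0L,  0L, -3L,  5L,  2L, -2L,  0L, -3L, -2L,  1L,  0L, -3L, -1L,  0L, -1L, -2L, -1L, -2L,
  -1L,  0L,  0L,  2L, -4L,  2L,  5L, -2L,  0L, -3L, -3L,  1L, -2L, -3L, -1L,  0L, -1L, -3L, -2L, -2L,
   0L, -2L,  0L, -1L, -3L, -2L, -2L,  6L, -2L, -4L, -4L, -2L, -3L, -3L, -2L,  0L, -2L, -2L, -3L, -3L,
  -2L,  0L,  1L, -1L, -3L,  0L,  0L, -2L,  8L, -3L, -3L, -1L, -2L, -1L, -2L, -1L, -2L, -2L,  2L, -3L,
  -1L, -3L, -3L, -3L, -1L, -3L, -3L, -4L, -3L,  4L,  2L, -3L,  1L,  0L, -3L, -2L, -1L, -3L, -1L,  3L,
  -1L, -2L, -3L, -4L, -1L, -2L, -3L, -4L, -3L,  2L,  4L, -2L,  2L,  0L, -3L, -2L, -1L, -2L, -1L,  1L,
  -1L,  2L,  0L, -1L, -3L,  1L,  1L, -2L, -1L, -3L, -2L,  5L, -1L, -3L, -1L,  0L, -1L, -3L, -2L, -2L,
  -1L, -1L, -2L, -3L, -1L,  0L, -2L, -3L, -2L,  1L,  2L, -1L,  5L,  0L, -2L, -1L, -1L, -1L, -1L,  1L,
  -2L, -3L, -3L, -3L, -2L, -3L, -3L, -3L, -1L,  0L,  0L, -3L,  0L,  6L, -4L, -2L, -2L,  1L,  3L, -1L,
  -1L, -2L, -2L, -1L, -3L, -1L, -1L, -2L, -2L, -3L, -3L, -1L, -2L, -4L,  7L, -1L, -1L, -4L, -3L, -2L,
   1L, -1L,  1L,  0L, -1L,  0L,  0L,  0L, -1L, -2L, -2L,  0L, -1L, -2L, -1L,  4L,  1L, -3L, -2L, -2L,
   0L, -1L,  0L, -1L, -1L, -1L, -1L, -2L, -2L, -1L, -1L, -1L, -1L, -2L, -1L,  1L,  5L, -2L, -2L,  0L,
  -3L, -3L, -4L, -4L, -2L, -2L, -3L, -2L, -2L, -3L, -2L, -3L, -1L,  1L, -4L, -3L, -2L, 11L,  2L, -3L,
  -2L, -2L, -2L, -3L, -2L, -1L, -2L, -3L,  2L, -1L, -1L, -2L, -1L,  3L, -3L, -2L, -2L,  2L,  7L, -1L,
   0L, -3L, -3L, -3L, -1L, -2L, -2L, -3L, -3L,  3L,  1L, -2L,  1L, -1L, -2L, -2L,  0L, -3L, -1L,  4L),
  nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")))
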