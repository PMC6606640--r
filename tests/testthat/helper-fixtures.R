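# Shared fixtures, built in code at test time.

# Toy FVIII-style family alignment around the L69V hemophilia variant:
# human carries L at ungapped position 3, while chimpanzee, mouse and rat
# carry V at the same column (a compensated deviation), plus one species
# with an unrelated residue and gap structure.
toy_fviii_alignment <- function() {
  ortholog_alignment(
    ids = c("HUMAN", "CHIMP", "MOUSE", "RAT", "FROG"),
    seqs = c(HUMAN = "AK-LDE",
             CHIMP = "AKQVDE",
             MOUSE = "AK-VDE",
             RAT   = "GK-VDE",
             FROG  = "AR-IDE"),
    human_id = "HUMAN")
}

toy_fviii_variants <- function() {
  data.frame(gene = "F8",
             wt = c("L", "A", "D"),
             pos = c(3L, 1L, 4L),
             mut = c("V", "G", "E"),
             severity = c("mild", "severe", "mild"),
             stringsAsFactors = FALSE)
}

write_tsv_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent two-sided Fisher oracle: enumerate every margin-preserving
# 2x2 table, point probabilities from log binomial coefficients, and sum
# those no larger than the observed one (same 1e-7 tie tolerance as the
# contract under test).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  probs <- exp(logp)
  obs <- probs[support == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

small_sim_config <- function(seed = 42L, n_variants = 50L,
                             cohort_size = 150L, seq_length = 250L, ...) {
  simulation_config(seed = seed, n_species = 12L, seq_length = seq_length,
                    n_variants = n_variants, cohort_size = cohort_size, ...)
}
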