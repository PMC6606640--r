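toy_genotypes <- function() {
  data.frame(
    individual_id = c("I1", "I1", "I2", "I2", "I2", "I3"),
    superpopulation = c("AFR", "AFR", "EUR", "EUR", "EUR", "EAS"),
    gene = c("F12", "VWF", "F8", "VWF", "F2", "VWF"),
    variant_key = c("A10G", "L5V", "L69V", "L5V", "R8Q", "L5V"),
    pathogenicity = c("neutral", "pathogenic", "pathogenic", "pathogenic",
                      "unknown", "neutral"),
    stringsAsFactors = FALSE)
}

test_that("gene panels validate membership and read from file", {
  expect_error(gene_panel(c("F8", "F8")), "unique")
  expect_error(gene_panel(c("VWF", "F2"), focal_genes = "F8"), "focal")
  p <- default_hemostasis_panel()
  expect_length(p$genes, 19L)
  expect_true(all(c("F8", "F9", "VWF", "F12", "KNG1", "GP1BB") %in% p$genes))
  expect_equal(p$focal_genes, c("F8", "F9"))

  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# panel", p$genes), f)
  expect_equal(read_gene_panel(f)$genes, p$genes)
})

test_that("per-individual burdens count variants, proteins and composition", {
  b <- individual_burdens(toy_genotypes(), default_hemostasis_panel())
  expect_equal(b$individual_id, c("I1", "I2", "I3"))
  i2 <- b[b$individual_id == "I2", ]
  expect_equal(i2$n_variants_total, 3L)
  expect_equal(i2$n_mutated_proteins, 3L)
  expect_equal(i2$n_variants_excl_focal, 2L)  # L69V is in focal F8
  expect_equal(i2$n_pathogenic, 2L)
  expect_equal(i2$n_unknown, 1L)
  # invariant: composition partitions the total
  expect_equal(b$n_pathogenic + b$n_neutral + b$n_unknown,
               b$n_variants_total)
  expect_true(all(b$n_mutated_proteins <= 19L))
  expect_true(all(b$n_variants_excl_focal <= b$n_variants_total))
  # equality iff no focal-gene variants
  expect_equal(b$n_variants_excl_focal == b$n_variants_total,
               b$individual_id != "I2")
})

test_that("off-panel genes are dropped with a warning", {
  g <- toy_genotypes()
  g$gene[1] <- "NOTAGENE"
  expect_warning(b <- individual_burdens(g, default_hemostasis_panel()),
                 "NOTAGENE")
  expect_equal(b$n_variants_total[b$individual_id == "I1"], 1L)
})

test_that("gene prevalence is zero-filled over the panel", {
  prev <- gene_mutation_prevalence(toy_genotypes(),
                                   default_hemostasis_panel())
  expect_equal(nrow(prev), 19L)
  expect_equal(prev$n_individuals[prev$gene == "VWF"], 3L)
  expect_equal(prev$n_individuals[prev$gene == "KNG1"], 0L)
  expect_equal(prev$n_individuals[prev$gene == "F8"], 1L)
})

test_that("cis/trans labels compare gene symbols case-insensitively", {
  expect_equal(cis_trans_label("F8", "F8"), "cis")
  expect_equal(cis_trans_label("VWF", "F8"), "trans")
  expect_equal(cis_trans_label("f8", "F8"), "cis")
  expect_equal(cis_trans_label(c("F8", "VWF", "F9"), "F9"),
               c("trans", "trans", "cis"))
})

test_that("variant background ranges match a brute-force recount", {
  set.seed(77)
  cfg <- small_sim_config(seed = 78L, cohort_size = 120L)
  panel <- default_hemostasis_panel()
  geno <- gen_cohort(cfg, panel)$genotypes
  ranges <- variant_background_ranges(geno, panel)
  expect_true(all(ranges$min_background <= ranges$max_background))
  expect_true(all(ranges$n_carriers >= 1L))
  expect_equal(ranges$multi_carrier, ranges$n_carriers >= 2L)
  # brute force: recount every carrier's background per variant
  for (i in sample(nrow(ranges), min(25, nrow(ranges)))) {
    hit <- geno$gene == ranges$gene[i] &
      geno$variant_key == ranges$variant_key[i]
    carriers <- unique(geno$individual_id[hit])
    bg <- vapply(carriers, function(id) {
      mine <- geno[geno$individual_id == id, ]
      sum(!(mine$gene == ranges$gene[i] &
              mine$variant_key == ranges$variant_key[i]))
    }, 0L)
    expect_equal(ranges$n_carriers[i], length(carriers))
    expect_equal(ranges$min_background[i], min(bg))
    expect_equal(ranges$max_background[i], max(bg))
    bgp <- vapply(carriers, function(id) {
      mine <- geno[geno$individual_id == id &
                     geno$pathogenicity == "pathogenic", ]
      sum(!(mine$gene == ranges$gene[i] &
              mine$variant_key == ranges$variant_key[i]))
    }, 0L)
    expect_equal(ranges$min_background_pathogenic[i], min(bgp))
    expect_equal(ranges$max_background_pathogenic[i], max(bgp))
  }
})

test_that("simple background range cases are exact", {
  g <- data.frame(
    individual_id = c(rep("I1", 5), rep("I2", 10)),
    superpopulation = "EUR",
    gene = c("F8", "VWF", "F2", "F5", "F7",
             "F8", "VWF", "F2", "F5", "F7", "F10", "F11", "F12", "FGA",
             "FGB"),
    variant_key = c("L69V", paste0("K", 1:4, "R"),
                    "L69V", paste0("K", 1:9, "R")),
    pathogenicity = "unknown", stringsAsFactors = FALSE)
  r <- variant_background_ranges(g, default_hemostasis_panel())
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_carriers, 2L)
  expect_equal(r$min_background, 4L)
  expect_equal(r$max_background, 9L)
  expect_true(r$multi_carrier)
})

test_that("composition summary tabulates combinations and carrier fraction", {
  b <- data.frame(individual_id = c("I1", "I2", "I3"),
                  superpopulation = c("AFR", "AFR", "EUR"),
                  n_variants_total = c(5L, 5L, 4L),
                  n_variants_excl_focal = c(5L, 5L, 4L),
                  n_mutated_proteins = c(3L, 3L, 2L),
                  n_pathogenic = c(2L, 2L, 0L),
                  n_neutral = c(3L, 3L, 3L),
                  n_unknown = c(0L, 0L, 1L), stringsAsFactors = FALSE)
  cs <- pathogenic_composition_summary(b)
  expect_equal(sum(cs$combinations$n_individuals), 3L)
  row <- cs$combinations[cs$combinations$n_pathogenic == 2, ]
  expect_equal(row$n_individuals, 2L)  # identical individuals collapse
  expect_equal(row$share_AFR, 1)
  shares <- as.matrix(cs$combinations[, grep("^share_",
                                             names(cs$combinations))])
  expect_equal(unname(rowSums(shares)), rep(1, nrow(shares)))
  expect_equal(cs$fraction_with_pathogenic, 2 / 3)
  # unknowns count as neutral by default, separate in strict mode
  expect_equal(cs$combinations$n_neutral[cs$combinations$n_pathogenic == 0],
               4L)
  strict <- pathogenic_composition_summary(b, unknown_as_neutral = FALSE)
  expect_equal(
    strict$combinations$n_neutral[strict$combinations$n_pathogenic == 0],
    3L)

  empty <- pathogenic_composition_summary(b[0, ])
  expect_equal(nrow(empty$combinations), 0L)
})
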