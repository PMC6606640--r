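#' Configuration for the synthetic-study generator
#'
#' Bundles every knob of the synthetic data that the pipeline's analyses
#' assume, with defaults mirroring the scale of the hemophilia A study
#' system: 971 pathogenic missense variants of which 122 are compensated,
#' a cohort of 1233 males spread over five superpopulations, and a 19-gene
#' hemostasis panel. Ground truth (planted compensation status, group
#' parameters, per-site targets) is recorded alongside the generated data
#' so recovery can be checked exactly.
#'
#' @param seed Integer seed; all generators derive their randomness from it.
#' @param gene Gene symbol the alignment and variant set belong to.
#' @param n_species Number of rows in the ortholog alignment (human
#'   included), >= 2.
#' @param seq_length Human protein length in residues; must be >=
#'   `n_variants` (variant positions are drawn without replacement).
#' @param site_entropy Optional numeric vector (length `seq_length`) of
#'   per-site target Shannon entropies in `[0, log2(20)]`; by default drawn
#'   from a right-skewed Beta profile (most sites conserved, a tail of
#'   variable sites).
#' @param n_variants Number of pathogenic missense variants to plant.
#' @param cpd_fraction Fraction of variants planted as compensated.
#' @param ddg_params List with `cpd` and `nocpd` elements, each
#'   `c(mean, sd)` of the Gaussian generating ddg (kcal/mol); compensated
#'   variants are milder (default means 0.8 vs 1.8, a 1.0 kcal/mol shift).
#' @param rsa_params List with `cpd` and `nocpd` elements, each
#'   `c(min, max)` of the uniform generating relative solvent accessibility
#'   (percent); non-compensated variants sit in more buried positions.
#' @param severity_slope,severity_intercept Logistic model of clinical
#'   severity: `P(severe) = plogis(intercept + slope * ddg)`. Slope 0
#'   decouples severity from stability.
#' @param cohort_size Number of individuals in the population cohort.
#' @param superpop_weights Named sampling weights over AFR/AMR/EAS/EUR/SAS
#'   (normalized internally; defaults approximate the male composition of
#'   the source population panel).
#' @param gene_prevalence Optional named vector over panel genes: target
#'   probability that an individual carries >= 1 variant in that gene.
#'   Defaults span near-universal (VWF, F12) to rare (KNG1, GP1BB).
#' @param sites_per_gene Number of segregating variant sites per panel gene.
#' @param pathogenic_prob Probability that a cohort variant site is
#'   pathogenic.
#' @param pop_freq_multiplier Optional named per-superpopulation multiplier
#'   on site carrier frequencies.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 20260101L,
                              gene = "F8",
                              n_species = 24L,
                              seq_length = 2332L,
                              site_entropy = NULL,
                              n_variants = 971L,
                              cpd_fraction = 122 / 971,
                              ddg_params = list(cpd = c(mean = 0.8, sd = 1.0),
                                                nocpd = c(mean = 1.8, sd = 1.2)),
                              rsa_params = list(cpd = c(min = 5, max = 95),
                                                nocpd = c(min = 0, max = 70)),
                              severity_slope = 1.0,
                              severity_intercept = -1.6,
                              cohort_size = 1233L,
                              superpop_weights = c(AFR = 0.27, AMR = 0.14,
                                                   EAS = 0.20, EUR = 0.19,
                                                   SAS = 0.20),
                              gene_prevalence = NULL,
                              sites_per_gene = 6L,
                              pathogenic_prob = 0.25,
                              pop_freq_multiplier = NULL) {
  stopifnot(n_species >= 2L, seq_length >= n_variants, n_variants >= 0L,
            cpd_fraction >= 0, cpd_fraction <= 1, cohort_size >= 0L,
            sites_per_gene >= 1L,
            pathogenic_prob >= 0, pathogenic_prob <= 1)
  if (!is.null(site_entropy)) {
    stopifnot(length(site_entropy) == seq_length)
    if (any(site_entropy < 0) || any(site_entropy > log2(20))) {
      stop("site entropies must lie in [0, log2(20)]")
    }
  }
  superpop_weights <- superpop_weights / sum(superpop_weights)
  structure(list(seed = as.integer(seed), gene = gene,
                 n_species = as.integer(n_species),
                 seq_length = as.integer(seq_length),
                 site_entropy = site_entropy,
                 n_variants = as.integer(n_variants),
                 cpd_fraction = cpd_fraction,
                 ddg_params = ddg_params, rsa_params = rsa_params,
                 severity_slope = severity_slope,
                 severity_intercept = severity_intercept,
                 cohort_size = as.integer(cohort_size),
                 superpop_weights = superpop_weights,
                 gene_prevalence = gene_prevalence,
                 sites_per_gene = as.integer(sites_per_gene),
                 pathogenic_prob = pathogenic_prob,
                 pop_freq_multiplier = pop_freq_multiplier),
            class = "simulation_config")
}

# Solve the dominant-residue frequency q of a two-state mixture (one
# dominant residue, k equiprobable alternatives) whose entropy matches a
# target h. Approximate by construction; exact at h = 0 and h = log2(k+1).
mixture_dominant_freq <- function(h, k) {
  if (h <= 0) return(1)
  hmax <- log2(k + 1)
  if (h >= hmax) return(1 / (k + 1))
  ent <- function(q) -q * log2(q) - (1 - q) * log2((1 - q) / k) - h
  stats::uniroot(ent, lower = 1 / (k + 1), upper = 1 - 1e-9,
                 tol = 1e-9)$root
}

#' Generate a synthetic ortholog alignment with planted compensations
#'
#' Builds a human sequence plus ortholog rows whose per-site variability
#' approximates a target entropy profile (a dominant residue — the human
#' one — with a tunable frequency over a small alternative set). A set of
#' pathogenic missense variants is drawn; for those planted as compensated,
#' the mutant residue is written into 1–3 non-human rows at the variant's
#' column, and for the rest the mutant residue is guaranteed absent from
#' all non-human rows at that column. Ortholog-only insertion columns (in
#' which the human row is gapped) and scattered deletion gaps make the
#' position-to-column mapping non-trivial; variant columns are kept
#' gap-free in the supporting rows.
#'
#' @param config A [simulation_config()].
#' @return List with `aln` (an `ortholog_alignment`, human row `"HUMAN"`)
#'   and `truth` (list: `variants` data.frame with planted `is_cpd` and
#'   `supporting_species`, `site_entropy` targets, and the generating
#'   parameters).
#' @export
gen_msa <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$seq_length
  n_orth <- config$n_species - 1L
  human <- sample(AA_CANONICAL, L, replace = TRUE)
  h <- config$site_entropy
  if (is.null(h)) h <- log2(20) * stats::rbeta(L, 1.1, 3.2)
  # per-site mixture: human residue dominant, k alternatives
  mat <- matrix("", nrow = n_orth, ncol = L)
  alt_sets <- vector("list", L)
  for (j in seq_len(L)) {
    k <- min(19L, max(3L, ceiling(2^h[j]) - 1L))
    q <- mixture_dominant_freq(h[j], k)
    alts <- sample(setdiff(AA_CANONICAL, human[j]), k)
    alt_sets[[j]] <- alts
    pick <- stats::runif(n_orth) < q
    mat[, j] <- ifelse(pick, human[j],
                       alts[sample.int(k, n_orth, replace = TRUE)])
  }
  # variants and planted compensation status
  nv <- config$n_variants
  pos <- sort(sample.int(L, nv))
  wt <- human[pos]
  mut <- vapply(wt, function(w) sample(setdiff(AA_CANONICAL, w), 1L), "")
  is_cpd <- rep(FALSE, nv)
  if (nv > 0L) {
    is_cpd[sample.int(nv, round(config$cpd_fraction * nv))] <- TRUE
  }
  species <- paste0("SP", sprintf("%02d", seq_len(n_orth)))
  support <- character(nv)
  for (i in seq_len(nv)) {
    j <- pos[i]
    carriers <- mat[, j] == mut[i]
    if (is_cpd[i]) {
      if (!any(carriers)) {
        rows <- sample.int(n_orth, sample(1:3, 1L))
        mat[rows, j] <- mut[i]
      }
      support[i] <- paste(species[mat[, j] == mut[i]], collapse = ",")
    } else if (any(carriers)) {
      # scrub the mutant residue so the variant stays non-compensated
      repl <- setdiff(c(human[j], alt_sets[[j]]), mut[i])
      mat[carriers, j] <- sample(repl, sum(carriers), replace = TRUE)
    }
  }
  # deletion gaps in ortholog rows, away from variant columns
  gap_ok <- setdiff(seq_len(L), pos)
  n_del <- round(0.01 * n_orth * length(gap_ok))
  del_rows <- sample.int(n_orth, n_del, replace = TRUE)
  del_cols <- sample(gap_ok, n_del, replace = TRUE)
  mat[cbind(del_rows, del_cols)] <- "-"
  # ortholog-only insertion columns (human gapped)
  full <- rbind(human, mat)
  n_ins <- max(1L, round(0.02 * L))
  ins_after <- sort(sample(0:L, n_ins, replace = TRUE))
  pieces <- list()
  prev <- 0L
  for (b in seq_along(ins_after)) {
    pieces[[length(pieces) + 1L]] <-
      full[, seq_len(ins_after[b] - prev) + prev, drop = FALSE]
    ins_col <- c("-", ifelse(stats::runif(n_orth) < 0.3,
                             sample(AA_CANONICAL, n_orth, replace = TRUE),
                             "-"))
    pieces[[length(pieces) + 1L]] <- matrix(ins_col, ncol = 1L)
    prev <- ins_after[b]
  }
  if (prev < L) pieces[[length(pieces) + 1L]] <-
    full[, (prev + 1L):L, drop = FALSE]
  full <- do.call(cbind, pieces)
  seqs <- apply(full, 1L, paste, collapse = "")
  aln <- ortholog_alignment(c("HUMAN", species), seqs, "HUMAN")
  truth <- list(
    variants = data.frame(gene = rep(config$gene, nv), wt = wt, pos = pos,
                          mut = mut, is_cpd = is_cpd,
                          supporting_species = support,
                          stringsAsFactors = FALSE),
    site_entropy = h,
    gene = config$gene, seed = config$seed)
  list(aln = aln, truth = truth)
}

#' Generate variant and molecular-property tables from planted truth
#'
#' Draws the molecular-impact values the study's external tools would
#' provide: ddg from group-specific Gaussians (compensated variants
#' milder), rsa from group-specific uniform ranges, and a clinical
#' severity label from a logistic model on ddg. All generating parameters
#' are copied into the returned truth.
#'
#' @param config A [simulation_config()].
#' @param truth Truth list from [gen_msa()].
#' @return List with `variants` (gene, wt, pos, mut, severity,
#'   pathogenicity), `props` (gene, wt, pos, mut, ddg, rsa) and `truth`
#'   (input truth extended with `ddg`, `rsa`, `severity` and the model
#'   parameters).
#' @export
gen_variant_and_property_tables <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  tv <- truth$variants
  grp <- ifelse(tv$is_cpd, "cpd", "nocpd")
  dp <- config$ddg_params
  rp <- config$rsa_params
  n <- nrow(tv)
  ddg <- stats::rnorm(n,
                      mean = vapply(grp, function(g) dp[[g]][["mean"]], 0),
                      sd = vapply(grp, function(g) dp[[g]][["sd"]], 0))
  rsa <- stats::runif(n,
                      min = vapply(grp, function(g) rp[[g]][["min"]], 0),
                      max = vapply(grp, function(g) rp[[g]][["max"]], 0))
  p_severe <- stats::plogis(config$severity_intercept +
                              config$severity_slope * ddg)
  severity <- ifelse(stats::runif(n) < p_severe, "severe", "mild")
  variants <- data.frame(gene = tv$gene, wt = tv$wt, pos = tv$pos,
                         mut = tv$mut, severity = severity,
                         pathogenicity = "pathogenic",
                         stringsAsFactors = FALSE)
  props <- data.frame(gene = tv$gene, wt = tv$wt, pos = tv$pos,
                      mut = tv$mut, ddg = ddg, rsa = rsa,
                      stringsAsFactors = FALSE)
  truth$ddg <- ddg
  truth$rsa <- rsa
  truth$severity <- severity
  truth$ddg_params <- dp
  truth$rsa_params <- rp
  truth$severity_model <- c(slope = config$severity_slope,
                            intercept = config$severity_intercept)
  list(variants = variants, props = props, truth = truth)
}

default_gene_prevalence <- function(panel) {
  base <- c(VWF = 0.99, F12 = 0.97, KNG1 = 0.03, GP1BB = 0.02,
            F8 = 0.30, F9 = 0.20)
  prev <- stats::setNames(rep(NA_real_, length(panel$genes)), panel$genes)
  hit <- intersect(names(base), panel$genes)
  prev[hit] <- base[hit]
  # remaining genes: intermediate prevalences; with the near-universal and
  # rare genes above this puts the modal number of mutated proteins per
  # individual at 6-8 and the variant burden in the 5-20 range
  rest <- which(is.na(prev))
  prev[rest] <- seq(0.15, 0.55, length.out = length(rest))
  prev
}

#' Generate a synthetic population cohort over a gene panel
#'
#' Emulates the per-individual missense genotypes of a male population
#' cohort: each panel gene carries a fixed set of segregating variant
#' sites whose carrier frequencies are calibrated so that the probability
#' of carrying at least one variant in the gene matches the configured
#' per-gene prevalence; individuals draw each site independently.
#' Pathogenicity is a per-site Bernoulli property and superpopulation
#' labels are sampled from the configured weights.
#'
#' @param config A [simulation_config()].
#' @param panel A `gene_panel`.
#' @return List with `genotypes` (long `data.frame`: `individual_id`,
#'   `superpopulation`, `gene`, `variant_key`, `pathogenicity`) and
#'   `truth` (list: per-gene prevalence targets, site table with
#'   frequencies and pathogenicity, expected per-individual variant count).
#' @export
gen_cohort <- function(config, panel) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(panel, "gene_panel"))
  set.seed(config$seed + 2L)
  prev <- config$gene_prevalence
  if (is.null(prev)) prev <- default_gene_prevalence(panel)
  stopifnot(all(panel$genes %in% names(prev)))
  prev <- prev[panel$genes]
  k <- config$sites_per_gene
  sites <- do.call(rbind, lapply(panel$genes, function(g) {
    wt <- sample(AA_CANONICAL, k, replace = TRUE)
    pos <- sample.int(800L, k)
    mut <- vapply(wt, function(w) sample(setdiff(AA_CANONICAL, w), 1L), "")
    data.frame(gene = g,
               variant_key = paste0(wt, pos, mut),
               freq = 1 - (1 - prev[[g]])^(1 / k),
               pathogenicity = ifelse(
                 stats::runif(k) < config$pathogenic_prob,
                 "pathogenic", "neutral"),
               stringsAsFactors = FALSE)
  }))
  n <- config$cohort_size
  if (n == 0L) {
    geno <- data.frame(individual_id = character(),
                       superpopulation = character(), gene = character(),
                       variant_key = character(),
                       pathogenicity = character(), stringsAsFactors = FALSE)
    return(list(genotypes = geno,
                truth = list(gene_prevalence = prev, sites = sites,
                             expected_variants_per_individual =
                               sum(sites$freq))))
  }
  ids <- sprintf("IND%04d", seq_len(n))
  pops <- sample(names(config$superpop_weights), n, replace = TRUE,
                 prob = config$superpop_weights)
  mult <- config$pop_freq_multiplier
  if (is.null(mult)) {
    mult <- stats::setNames(rep(1, length(config$superpop_weights)),
                            names(config$superpop_weights))
  }
  carry <- matrix(stats::runif(n * nrow(sites)), nrow = n) <
    outer(unname(mult[pops]), sites$freq)
  idx <- which(carry, arr.ind = TRUE)
  geno <- data.frame(individual_id = ids[idx[, 1L]],
                     superpopulation = pops[idx[, 1L]],
                     gene = sites$gene[idx[, 2L]],
                     variant_key = sites$variant_key[idx[, 2L]],
                     pathogenicity = sites$pathogenicity[idx[, 2L]],
                     stringsAsFactors = FALSE)
  geno <- geno[order(geno$individual_id, geno$gene, geno$variant_key), ,
               drop = FALSE]
  rownames(geno) <- NULL
  geno$superpopulation <- normalize_superpopulation(geno$superpopulation)
  geno$pathogenicity <- normalize_pathogenicity(geno$pathogenicity)
  list(genotypes = geno,
       truth = list(gene_prevalence = prev, sites = sites,
                    superpopulations = stats::setNames(pops, ids),
                    expected_variants_per_individual = sum(sites$freq)))
}

#' Generate and write a complete synthetic study to disk
#'
#' Runs [gen_msa()], [gen_variant_and_property_tables()] and
#' [gen_cohort()] and writes `msa_<gene>.fasta`, `variants.tsv`,
#' `props.tsv`, `genotypes.tsv`, `panel.txt` and `truth.json` under
#' `out_dir`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param panel A `gene_panel` for the cohort.
#' @return Invisibly, the list of generated objects (aln, variants, props,
#'   genotypes, truth).
#' @export
simulate_study <- function(config, out_dir,
                           panel = default_hemostasis_panel()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msa <- gen_msa(config)
  tabs <- gen_variant_and_property_tables(config, msa$truth)
  cohort <- gen_cohort(config, panel)
  write_msa_fasta(msa$aln,
                  file.path(out_dir, paste0("msa_", config$gene, ".fasta")))
  write_variant_table(tabs$variants, file.path(out_dir, "variants.tsv"))
  utils::write.table(tabs$props, file.path(out_dir, "props.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$genotypes, file.path(out_dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(panel$genes, file.path(out_dir, "panel.txt"))
  truth <- tabs$truth
  truth$cohort <- cohort$truth
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(aln = msa$aln, variants = tabs$variants,
                 props = tabs$props, genotypes = cohort$genotypes,
                 truth = truth))
}
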