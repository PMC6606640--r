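#' Construct a hemostasis gene panel
#'
#' The genetic background of a focal coagulation-factor variant is counted
#' over a fixed panel of hemostasis genes. Symbols must be unique and the
#' focal genes must belong to the panel.
#'
#' @param genes Character vector of unique gene symbols.
#' @param focal_genes Subset of `genes` holding the focal coagulation
#'   factors (default FVIII and FIX).
#' @return A `gene_panel` object (list with `genes` and `focal_genes`).
#' @seealso [default_hemostasis_panel()]
#' @export
gene_panel <- function(genes, focal_genes = c("F8", "F9")) {
  genes <- trimws(as.character(genes))
  if (anyDuplicated(genes)) stop("panel gene symbols must be unique")
  focal_genes <- intersect(focal_genes, genes)
  if (length(focal_genes) == 0L) {
    stop("focal genes must be members of the panel")
  }
  structure(list(genes = genes, focal_genes = focal_genes),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("Gene panel: ", length(x$genes), " genes (focal: ",
      paste(x$focal_genes, collapse = ", "), ")\n", sep = "")
  cat(paste(x$genes, collapse = " "), "\n")
  invisible(x)
}

#' Default 19-gene hemostasis panel
#'
#' A representative panel of 19 hemostasis proteins — the coagulation
#' cascade factors, fibrinogen chains, von Willebrand factor, kininogen,
#' platelet glycoprotein Ib beta and the main natural anticoagulants —
#' with FVIII (F8) and FIX (F9) as focal genes. Any panel can be
#' substituted via [gene_panel()] or [read_gene_panel()].
#'
#' @return A `gene_panel` of 19 genes.
#' @export
default_hemostasis_panel <- function() {
  gene_panel(c("F2", "F5", "F7", "F8", "F9", "F10", "F11", "F12",
               "F13A1", "F13B", "FGA", "FGB", "FGG", "VWF", "KNG1",
               "GP1BB", "SERPINC1", "PROC", "PROS1"),
             focal_genes = c("F8", "F9"))
}

check_panel_genes <- function(genotypes, panel) {
  off <- !(genotypes$gene %in% panel$genes)
  if (any(off)) {
    warning("dropping ", sum(off), " genotype row(s) in genes outside the ",
            "panel: ", paste(unique(genotypes$gene[off]), collapse = ", "))
    genotypes <- genotypes[!off, , drop = FALSE]
  }
  genotypes
}

#' Per-individual missense burden over the panel
#'
#' Summarizes each individual's genetic background: how many panel variants
#' they carry, over how many distinct proteins, and the pathogenic/neutral
#' composition. Only individuals present in the genotype table appear (no
#' zero-filling). A protein counts as "mutated" for an individual when it
#' carries at least one missense variant in that gene.
#'
#' @param genotypes Genotype `data.frame` from [read_genotypes()] or
#'   [gen_cohort()].
#' @param panel A `gene_panel`; genotype rows outside the panel are dropped
#'   with a warning.
#' @return `data.frame` with one row per individual: `individual_id`,
#'   `superpopulation`, `n_variants_total`, `n_variants_excl_focal` (total
#'   minus variants in the focal genes), `n_mutated_proteins`,
#'   `n_pathogenic`, `n_neutral`, `n_unknown`.
#' @export
individual_burdens <- function(genotypes, panel) {
  genotypes <- check_panel_genes(genotypes, panel)
  if (nrow(genotypes) == 0L) {
    return(data.frame(individual_id = character(),
                      superpopulation = character(),
                      n_variants_total = integer(),
                      n_variants_excl_focal = integer(),
                      n_mutated_proteins = integer(),
                      n_pathogenic = integer(), n_neutral = integer(),
                      n_unknown = integer(), stringsAsFactors = FALSE))
  }
  split_rows <- split(genotypes, genotypes$individual_id)
  out <- lapply(split_rows, function(d) {
    data.frame(
      individual_id = d$individual_id[1L],
      superpopulation = as.character(d$superpopulation[1L]),
      n_variants_total = nrow(d),
      n_variants_excl_focal = sum(!(d$gene %in% panel$focal_genes)),
      n_mutated_proteins = length(unique(d$gene)),
      n_pathogenic = sum(d$pathogenicity == "pathogenic"),
      n_neutral = sum(d$pathogenicity == "neutral"),
      n_unknown = sum(!(d$pathogenicity %in% c("pathogenic", "neutral"))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$individual_id), , drop = FALSE]
}

#' Number of individuals carrying a variant in each panel gene
#'
#' For each gene of the panel, counts individuals with at least one
#' missense variant in that gene. Genes never mutated in the cohort are
#' reported with a zero count.
#'
#' @inheritParams individual_burdens
#' @return `data.frame` with columns `gene` (panel order) and
#'   `n_individuals`.
#' @export
gene_mutation_prevalence <- function(genotypes, panel) {
  genotypes <- check_panel_genes(genotypes, panel)
  pairs <- unique(genotypes[, c("individual_id", "gene")])
  counts <- table(factor(pairs$gene, levels = panel$genes))
  data.frame(gene = panel$genes,
             n_individuals = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Label a background variant as cis or trans to a focal gene
#'
#' A background variant is *cis* when it lies in the same protein as the
#' focal variant and *trans* when it lies in a different one. Matching is
#' case-insensitive. Vectorized over both arguments.
#'
#' @param background_gene Gene symbol(s) of background variants.
#' @param focal_gene Gene symbol(s) of the focal variant.
#' @return Character vector of `"cis"`/`"trans"`.
#' @examples
#' cis_trans_label(c("F8", "VWF"), "F8")
#' @export
cis_trans_label <- function(background_gene, focal_gene) {
  ifelse(toupper(trimws(background_gene)) == toupper(trimws(focal_gene)),
         "cis", "trans")
}

#' Background ranges of focal-gene variants across their carriers
#'
#' For every variant observed in a focal gene, computes each carrier's
#' genetic background — the number of panel variants that carrier holds
#' besides the focal variant itself (other same-gene, i.e. cis, variants
#' are kept) — and reports the minimum and maximum across carriers, both
#' for all background variants and restricted to pathogenic ones. Variants
#' carried by at least two individuals are flagged (`multi_carrier`),
#' since only those display between-carrier variability.
#'
#' @inheritParams individual_burdens
#' @param focal_genes Genes whose variants are treated as focal (default:
#'   the panel's focal genes).
#' @return `data.frame` with one row per focal variant: `gene`,
#'   `variant_key`, `n_carriers`, `min_background`, `max_background`,
#'   `min_background_pathogenic`, `max_background_pathogenic`,
#'   `multi_carrier`.
#' @export
variant_background_ranges <- function(genotypes, panel,
                                      focal_genes = panel$focal_genes) {
  genotypes <- check_panel_genes(genotypes, panel)
  focal <- genotypes[genotypes$gene %in% focal_genes, , drop = FALSE]
  if (nrow(focal) == 0L) {
    return(data.frame(gene = character(), variant_key = character(),
                      n_carriers = integer(), min_background = integer(),
                      max_background = integer(),
                      min_background_pathogenic = integer(),
                      max_background_pathogenic = integer(),
                      multi_carrier = logical(), stringsAsFactors = FALSE))
  }
  totals <- table(genotypes$individual_id)
  patho <- table(factor(
    genotypes$individual_id[genotypes$pathogenicity == "pathogenic"],
    levels = names(totals)))
  fv <- unique(focal[, c("gene", "variant_key")])
  rows <- lapply(seq_len(nrow(fv)), function(i) {
    hit <- focal$gene == fv$gene[i] & focal$variant_key == fv$variant_key[i]
    carriers <- unique(focal$individual_id[hit])
    is_patho <- any(focal$pathogenicity[hit] == "pathogenic")
    bg <- as.integer(totals[carriers]) - 1L  # minus the focal variant itself
    bgp <- as.integer(patho[carriers]) - as.integer(is_patho)
    data.frame(gene = fv$gene[i], variant_key = fv$variant_key[i],
               n_carriers = length(carriers),
               min_background = min(bg), max_background = max(bg),
               min_background_pathogenic = min(bgp),
               max_background_pathogenic = max(bgp),
               multi_carrier = length(carriers) >= 2L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Neutral/pathogenic composition of the cohort's backgrounds
#'
#' Tabulates the observed combinations of per-individual neutral and
#' pathogenic variant counts — one row per (n_neutral, n_pathogenic) pair,
#' with the number of individuals showing it and the share of each
#' superpopulation among them — and reports the fraction of individuals
#' carrying at least one pathogenic variant.
#'
#' @param burdens Burden `data.frame` from [individual_burdens()].
#' @param unknown_as_neutral Count unknown-pathogenicity variants as
#'   neutral (default `TRUE`: absence of a pathogenicity annotation is read
#'   as "not annotated pathogenic"). Set `FALSE` to keep them out of both
#'   counts.
#' @return A `composition_summary`: list with `combinations` (the
#'   `data.frame` described above, columns `n_neutral`, `n_pathogenic`,
#'   `n_individuals` and one `share_*` column per superpopulation level)
#'   and `fraction_with_pathogenic`.
#' @export
pathogenic_composition_summary <- function(burdens,
                                           unknown_as_neutral = TRUE) {
  pops <- c(SUPERPOPULATIONS, "other")
  if (nrow(burdens) == 0L) {
    comb <- data.frame(n_neutral = integer(), n_pathogenic = integer(),
                       n_individuals = integer(), stringsAsFactors = FALSE)
    for (p in pops) comb[[paste0("share_", p)]] <- numeric(0)
    return(structure(list(combinations = comb,
                          fraction_with_pathogenic = NA_real_),
                     class = "composition_summary"))
  }
  n_neutral <- burdens$n_neutral +
    if (unknown_as_neutral) burdens$n_unknown else 0L
  key <- paste(n_neutral, burdens$n_pathogenic, sep = "/")
  rows <- lapply(split(seq_len(nrow(burdens)), key), function(idx) {
    shares <- table(factor(burdens$superpopulation[idx], levels = pops))
    shares <- as.numeric(shares) / length(idx)
    row <- data.frame(n_neutral = n_neutral[idx[1L]],
                      n_pathogenic = burdens$n_pathogenic[idx[1L]],
                      n_individuals = length(idx),
                      stringsAsFactors = FALSE)
    for (j in seq_along(pops)) row[[paste0("share_", pops[j])]] <- shares[j]
    row
  })
  comb <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  comb <- comb[order(comb$n_neutral, comb$n_pathogenic), , drop = FALSE]
  rownames(comb) <- NULL
  structure(list(combinations = comb,
                 fraction_with_pathogenic = mean(burdens$n_pathogenic >= 1L)),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Background composition: ", nrow(x$combinations),
      " (n_neutral, n_pathogenic) combinations\n", sep = "")
  cat("fraction of individuals with >= 1 pathogenic variant: ",
      format(round(x$fraction_with_pathogenic, 3)), "\n", sep = "")
  invisible(x)
}
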