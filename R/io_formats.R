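#' Read an ortholog multiple sequence alignment from aligned FASTA
#'
#' Reads an aligned FASTA file of ortholog protein sequences and flags the
#' designated human row. All records must have the same aligned length.
#' Both `-` and `.` are treated as gap characters; residues are upper-cased.
#'
#' @param path Path to an aligned FASTA file with at least one record.
#' @param human_id Identifier of the human record. Matched against the full
#'   FASTA header and, as a fallback, against its first whitespace-delimited
#'   token; must match exactly one record.
#' @return An `ortholog_alignment` object: a list with elements `ids`
#'   (character vector of record identifiers, input order preserved), `seqs`
#'   (named character vector of aligned sequences), `human_index` (row index
#'   of the human record) and `human_id`.
#' @seealso [write_msa_fasta()], [map_position_to_column()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">HUMAN", "ACD-E", ">MOUSE", "ACDQE"), fa)
#' aln <- read_msa_fasta(fa, "HUMAN")
#' aln$human_index
#' @export
read_msa_fasta <- function(path, human_id) {
  stopifnot(is.character(path), length(path) == 1L,
            is.character(human_id), length(human_id) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 1L) stop("FASTA file contains no records: ", path)
  widths <- Biostrings::width(ss)
  if (length(unique(widths)) != 1L) {
    stop("not an alignment: records have unequal lengths (",
         paste(sort(unique(widths)), collapse = ", "), ") in ", path)
  }
  ids <- names(ss)
  seqs <- toupper(as.character(ss))
  ortholog_alignment(ids, seqs, human_id)
}

#' Construct an ortholog alignment object
#'
#' Low-level constructor used by [read_msa_fasta()] and the synthetic-data
#' generator. Validates equal aligned lengths and a unique human row.
#'
#' @param ids Character vector of record identifiers.
#' @param seqs Character vector of aligned sequences (same length as `ids`).
#' @param human_id Identifier of the human row; matched against `ids` or
#'   their first whitespace-delimited token.
#' @return An `ortholog_alignment` object.
#' @export
ortholog_alignment <- function(ids, seqs, human_id) {
  stopifnot(length(ids) == length(seqs), length(ids) >= 1L)
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("not an alignment: records have unequal lengths")
  }
  hit <- which(ids == human_id)
  if (length(hit) == 0L) {
    hit <- which(vapply(strsplit(ids, "\\s+"), `[`, "", 1L) == human_id)
  }
  if (length(hit) == 0L) stop("human record '", human_id, "' not found")
  if (length(hit) > 1L) stop("human record '", human_id, "' matches ",
                             length(hit), " records; must be unique")
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs,
                 human_index = hit, human_id = human_id),
            class = "ortholog_alignment")
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat("Ortholog alignment: ", length(x$ids), " sequences x ",
      aln_width(x), " columns\n", sep = "")
  cat("Human row: ", x$ids[x$human_index], " (index ", x$human_index,
      "), ungapped length ", human_length(x), "\n", sep = "")
  invisible(x)
}

#' Alignment width (number of columns)
#' @param aln An `ortholog_alignment`.
#' @return Integer number of alignment columns.
#' @export
aln_width <- function(aln) nchar(aln$seqs[[1L]])

#' Ungapped length of the human row
#' @param aln An `ortholog_alignment`.
#' @return Integer number of residues in the human sequence.
#' @export
human_length <- function(aln) {
  sum(!is_gap(strsplit(aln$seqs[[aln$human_index]], "")[[1L]]))
}

# gap predicate shared across the package: '-' and '.' are gaps
is_gap <- function(chars) chars == "-" | chars == "."

# alignment as a character matrix (rows = sequences)
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), ""))
}

#' Write an ortholog alignment to aligned FASTA
#'
#' @param aln An `ortholog_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a missense variant table
#'
#' Reads a tab-delimited table of pathogenic missense variants with columns
#' `gene`, `wt` (wild-type residue, one letter), `pos` (1-based position in
#' the human sequence), `mut` (mutant residue) and optional `severity`,
#' `pathogenicity`, `curated`, `ddg`, `rsa`. Lines starting with `#` are
#' comments. Residue letters are upper-cased; only the 20 canonical amino
#' acids are accepted and `wt` must differ from `mut`.
#'
#' Severity labels are normalized case- and whitespace-insensitively to
#' `mild`/`severe`; any other label (e.g. "moderate") maps to `unknown`
#' with a warning, and such variants are excluded from mild-vs-severe
#' analyses downstream. Pathogenicity is normalized the same way to
#' `pathogenic`/`neutral`/`unknown`.
#'
#' @param path Path to a TSV file with a header line.
#' @return A `data.frame` with columns `gene`, `wt`, `pos`, `mut`,
#'   `severity`, `pathogenicity` (factors with fixed levels) and any of the
#'   optional columns present in the file.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\twt\tpos\tmut\tseverity", "F8\tL\t69\tV\tmild"), tsv)
#' read_variant_table(tsv)
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("gene", "wt", "pos", "mut")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$gene <- trimws(as.character(df$gene))
  df$wt <- toupper(trimws(as.character(df$wt)))
  df$mut <- toupper(trimws(as.character(df$mut)))
  df$pos <- as.integer(df$pos)
  validate_variants(df)
  df$severity <- normalize_severity(if ("severity" %in% names(df))
    df$severity else rep(NA_character_, nrow(df)))
  df$pathogenicity <- normalize_pathogenicity(if ("pathogenicity" %in% names(df))
    df$pathogenicity else rep(NA_character_, nrow(df)))
  if ("curated" %in% names(df)) df$curated <- as.logical(df$curated)
  df
}

validate_variants <- function(df) {
  bad_aa <- !(df$wt %in% AA_CANONICAL) | !(df$mut %in% AA_CANONICAL)
  if (any(bad_aa)) {
    stop("non-canonical residue letter(s) in variant table, rows: ",
         paste(utils::head(which(bad_aa), 5L), collapse = ", "))
  }
  same <- df$wt == df$mut
  if (any(same)) {
    stop("wild-type equals mutant residue (not a missense change), rows: ",
         paste(utils::head(which(same), 5L), collapse = ", "))
  }
  if (any(is.na(df$pos)) || any(df$pos < 1L)) {
    stop("positions must be integers >= 1")
  }
  invisible(df)
}

SEVERITY_LEVELS <- c("mild", "severe", "unknown")
PATHOGENICITY_LEVELS <- c("pathogenic", "neutral", "unknown")

#' Normalize clinical severity labels
#'
#' Case- and whitespace-insensitive mapping to `mild`/`severe`; anything else
#' (including "moderate" and missing values) becomes `unknown`. Unrecognized
#' non-missing labels trigger one warning listing the offending values.
#'
#' @param x Character vector of raw severity labels.
#' @return Factor with levels `mild`, `severe`, `unknown`.
#' @export
normalize_severity <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  out <- ifelse(raw %in% c("mild", "severe"), raw, "unknown")
  odd <- !is.na(raw) & raw != "" & !(raw %in% c("mild", "severe", "unknown"))
  if (any(odd)) {
    warning("unrecognized severity label(s) mapped to 'unknown': ",
            paste(unique(raw[odd]), collapse = ", "))
  }
  factor(out, levels = SEVERITY_LEVELS)
}

normalize_pathogenicity <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  out <- ifelse(raw %in% c("pathogenic", "neutral"), raw, "unknown")
  factor(out, levels = PATHOGENICITY_LEVELS)
}

#' Write a variant table in the package's canonical TSV form
#'
#' @param df A variant `data.frame` as returned by [read_variant_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up a BLOSUM62 substitution score
#'
#' Returns the published BLOSUM62 log-odds score for a wild-type/mutant
#' amino-acid pair. The matrix is symmetric, so argument order is
#' irrelevant. Vectorized over both arguments.
#'
#' @param wt,mut One-letter amino-acid codes (canonical 20 only;
#'   case-insensitive).
#' @return Integer score(s).
#' @examples
#' blosum62("L", "V")  # 1 — the FVIII L69V substitution
#' blosum62("A", "A")  # 4
#' @export
blosum62 <- function(wt, mut) {
  wt <- toupper(as.character(wt))
  mut <- toupper(as.character(mut))
  bad <- !(wt %in% AA_CANONICAL) | !(mut %in% AA_CANONICAL)
  if (any(bad)) {
    stop("non-canonical amino acid letter(s): ",
         paste(unique(c(wt[bad], mut[bad])), collapse = ", "))
  }
  unname(BLOSUM62_MATRIX[cbind(wt, mut)])
}

#' Read per-individual missense genotypes over a gene panel
#'
#' Two dialects are supported. `long_tsv` expects a tab-delimited file with
#' columns `individual_id`, `superpopulation`, `gene`, `variant_key`
#' (wild-type + position + mutant, e.g. `L69V`) and optional `pathogenicity`.
#' `vcf` expects a VCF 4.x file with per-sample GT fields; the gene symbol
#' and the consequence class are taken from INFO tags (default `GENE` and
#' `CSQ`), and only records whose consequence contains "missense" are
#' ingested. Any non-reference genotype counts as carrying the variant,
#' once per individual (the cohort emulated here is male, so X-linked genes
#' are effectively hemizygous and zygosity is ignored).
#'
#' Duplicate (individual, gene, variant) rows are collapsed to one with a
#' warning.
#'
#' @param path Path to the genotype file.
#' @param dialect `"long_tsv"` (default) or `"vcf"`.
#' @param gene_tag,csq_tag INFO tag names used under the `vcf` dialect.
#' @return A `data.frame` with columns `individual_id`, `superpopulation`
#'   (factor: AFR/AMR/EAS/EUR/SAS/other), `gene`, `variant_key`,
#'   `pathogenicity`.
#' @export
read_genotypes <- function(path, dialect = c("long_tsv", "vcf"),
                           gene_tag = "GENE", csq_tag = "CSQ") {
  dialect <- match.arg(dialect)
  df <- switch(dialect,
               long_tsv = read_genotypes_tsv(path),
               vcf = read_genotypes_vcf(path, gene_tag, csq_tag))
  key <- paste(df$individual_id, df$gene, df$variant_key, sep = "\r")
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)),
            " duplicate (individual, gene, variant) row(s)")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df$superpopulation <- normalize_superpopulation(df$superpopulation)
  df$pathogenicity <- normalize_pathogenicity(df$pathogenicity)
  rownames(df) <- NULL
  df
}

SUPERPOPULATIONS <- c("AFR", "AMR", "EAS", "EUR", "SAS")

normalize_superpopulation <- function(x) {
  raw <- toupper(trimws(as.character(x)))
  out <- ifelse(raw %in% SUPERPOPULATIONS, raw, "other")
  factor(out, levels = c(SUPERPOPULATIONS, "other"))
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("individual_id", "gene", "variant_key")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("genotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"superpopulation" %in% names(df)) df$superpopulation <- "other"
  if (!"pathogenicity" %in% names(df)) df$pathogenicity <- "unknown"
  df[, c("individual_id", "superpopulation", "gene", "variant_key",
         "pathogenicity")]
}

read_genotypes_vcf <- function(path, gene_tag, csq_tag) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the 'vcf' dialect requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("VCF contains no records: ", path)
  gene <- vcfR::extract.info(v, gene_tag)
  csq <- vcfR::extract.info(v, csq_tag)
  if (all(is.na(gene))) {
    stop("no '", gene_tag, "' gene annotation found in VCF INFO field")
  }
  keep <- !is.na(csq) & grepl("missense", csq, ignore.case = TRUE)
  if (!any(keep)) {
    return(data.frame(individual_id = character(), superpopulation = character(),
                      gene = character(), variant_key = character(),
                      pathogenicity = character(), stringsAsFactors = FALSE))
  }
  gt <- vcfR::extract.gt(v)[keep, , drop = FALSE]
  gene <- gene[keep]
  vkey <- v@fix[keep, "ID"]
  noid <- is.na(vkey) | vkey == "."
  vkey[noid] <- paste0(v@fix[keep, "REF"], v@fix[keep, "POS"],
                       v@fix[keep, "ALT"])[noid]
  carried <- !is.na(gt) & grepl("[1-9]", gt)
  idx <- which(carried, arr.ind = TRUE)
  data.frame(individual_id = colnames(gt)[idx[, 2L]],
             superpopulation = "other",
             gene = gene[idx[, 1L]],
             variant_key = vkey[idx[, 1L]],
             pathogenicity = "unknown",
             stringsAsFactors = FALSE)
}

#' Read a gene panel file (one symbol per line)
#'
#' @param path Text file with one gene symbol per line; `#` comments and
#'   blank lines are ignored.
#' @param focal_genes Focal genes of the panel (default FVIII and FIX).
#' @return A `gene_panel` object (see [gene_panel()]).
#' @export
read_gene_panel <- function(path, focal_genes = c("F8", "F9")) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  gene_panel(lines, focal_genes)
}
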