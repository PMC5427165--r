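#' Cross-reference screen hits against GWAS-locus candidate genes
#'
#' Intersects a hit table with a list of genes lying in disease-associated
#' GWAS loci. Matching is by exact gene symbol after upper-casing; duplicate
#' locus entries collapse to one row per gene. The overlap carries the screen
#' scores of the matched genes when present in `hits`.
#'
#' @param hits A hit table ([call_hits()]) or any tibble with a `gene_id`
#'   column; when a `hit` column is present only flagged hits are matched.
#' @param locus_genes Tibble with a `gene` (or `gene_id`) column, optionally
#'   `chromosome` and `locus`.
#' @return Tibble of overlapping genes with locus annotation and any screen
#'   score columns.
#' @examples
#' hits <- tibble::tibble(gene_id = c("FERMT2", "ABC1"), hit = TRUE)
#' crossref_hits(hits, load_igap_locus_genes())
#' @export
crossref_hits <- function(hits, locus_genes) {
  hits <- as_tibble(hits)
  locus_genes <- as_tibble(locus_genes)
  if ("gene" %in% names(locus_genes) && !"gene_id" %in% names(locus_genes)) {
    locus_genes <- rename(locus_genes, gene_id = "gene")
  }
  stopifnot("gene_id" %in% names(hits), "gene_id" %in% names(locus_genes))
  if ("hit" %in% names(hits)) {
    hits <- filter(hits, .data$hit)
  }
  hits <- mutate(hits, .gene_key = toupper(.data$gene_id))
  locus_genes <- locus_genes |>
    mutate(.gene_key = toupper(.data$gene_id)) |>
    distinct(.data$.gene_key, .keep_all = TRUE) |>
    select(-"gene_id")
  out <- inner_join(hits, locus_genes, by = ".gene_key")
  out <- distinct(out, .data$.gene_key, .keep_all = TRUE)
  select(arrange(out, .data$.gene_key), -".gene_key")
}

#' Gene-wide Bonferroni filter of association records
#'
#' Applies the family-wise Bonferroni correction across the candidate genes
#' tested: the significance threshold is `family_alpha / m` and a record
#' survives iff its p-value is strictly below it. With the default 8-gene
#' candidate table and alpha 0.05 the exact threshold is 0.00625, displayed
#' rounded as 0.006.
#'
#' @param records Association tibble with a `p_value` column (see
#'   [load_igap_associations()]).
#' @param family_alpha Family-wise error rate (default 0.05).
#' @param m Number of genes tested; defaults to `nrow(records)`.
#' @return Tibble of surviving records, with attributes `threshold` (exact),
#'   `threshold_display` (rounded to 3 decimals), `family_alpha` and `m`.
#' @examples
#' surv <- bonferroni_filter(load_igap_associations())
#' surv$gene
#' attr(surv, "threshold_display")
#' @export
bonferroni_filter <- function(records, family_alpha = 0.05, m = NULL) {
  records <- as_tibble(records)
  stopifnot("p_value" %in% names(records))
  if (!(family_alpha > 0 && family_alpha < 1)) {
    abort("`family_alpha` must lie in (0, 1)", class = "appscreen_param_error")
  }
  if (is.null(m)) m <- nrow(records)
  if (m < 1) {
    abort("`m` must be at least 1 (no tests in the family)",
          class = "appscreen_input_error")
  }
  threshold <- family_alpha / m
  out <- filter(records, .data$p_value < threshold)
  attr(out, "threshold") <- threshold
  attr(out, "threshold_display") <- round(threshold, 3)
  attr(out, "family_alpha") <- family_alpha
  attr(out, "m") <- m
  out
}

#' Packaged candidate-gene association table (CSF amyloid-beta 42)
#'
#' Loads the packaged gene-level summary of associations between eight
#' AD-risk (IGAP) locus genes that scored in the extreme 5% of the APP
#' reporter screen and the cerebrospinal-fluid amyloid-beta 42 concentration:
#' for each gene its screen log2 fold-changes (YFP and mCherry, mean and SD),
#' the most strongly associated SNP, its effect estimate on standardized log
#' CSF amyloid-beta 42, and the association p-value. `PVRIG` is listed under
#' that symbol (alias MGC2463).
#'
#' @param path Optional path to an alternative table with the same columns.
#' @return Tibble with columns `gene`, `chromosome`, `locus`, `yfp_log2fc`,
#'   `yfp_log2fc_sd`, `mcherry_log2fc`, `mcherry_log2fc_sd`, `snp`, `beta`,
#'   `p_value`.
#' @examples
#' load_igap_associations()
#' @export
load_igap_associations <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "igap_csf_abeta42_associations.tsv",
                        package = "appscreen", mustWork = TRUE)
  }
  records <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("gene", "chromosome", "locus", "snp", "beta", "p_value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("association table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "appscreen_parse_error")
  }
  bad <- which(!is.finite(records$p_value) | records$p_value <= 0 |
                 records$p_value > 1)
  if (length(bad) > 0) {
    abort(sprintf("invalid p-value in association table row(s): %s",
                  paste(bad, collapse = ", ")),
          class = "appscreen_parse_error")
  }
  records
}

#' Packaged GWAS-locus gene list
#'
#' Genes falling in AD-risk GWAS loci, as shipped with the package (the
#' subset covered by the association table; supply your own list for a full
#' locus catalogue).
#'
#' @param path Optional path to an alternative list (`chromosome`, `locus`,
#'   `gene`).
#' @return Tibble with columns `chromosome`, `locus`, `gene`.
#' @export
load_igap_locus_genes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "igap_locus_genes.tsv",
                        package = "appscreen", mustWork = TRUE)
  }
  readr::read_tsv(path, show_col_types = FALSE)
}
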