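#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / ((length/1000) * (total_mapped/1e6))`. Vectorized over
#' genes; `total_mapped` is the library size of the condition (whether that
#' counts reads mapped to coding sequences only or genome-wide is an input
#' choice, not guessed here).
#'
#' @param count read counts.
#' @param gene_length_bp gene lengths in bp (> 0).
#' @param total_mapped total mapped reads of the condition (> 0).
#' @return RPKM values.
#' @export
rpkm <- function(count, gene_length_bp, total_mapped) {
  if (any(gene_length_bp <= 0)) stop("gene lengths must be positive")
  if (any(total_mapped <= 0)) stop("library size must be positive")
  count / ((gene_length_bp / 1000) * (total_mapped / 1e6))
}

#' Cured-versus-infected expression fold change
#'
#' `rpkm_cured / rpkm_infected`, rounded half-up to 2 decimals (the printed
#' table convention). Undefined (`NA`) when the infected level is zero.
#'
#' @param rpkm_cured RPKM in the cured condition.
#' @param rpkm_infected RPKM in the infected condition.
#' @return fold increase (cured), 2 decimals; `NA` where undefined.
#' @export
fold_change <- function(rpkm_cured, rpkm_infected) {
  out <- ifelse(rpkm_infected > 0,
                round_half_up(rpkm_cured / rpkm_infected, 2), NA_real_)
  out
}

#' Defense-gene expression report
#'
#' Table of RPKM levels in both conditions and the fold increase in the
#' cured strain, for a supplied gene list, in the supplied order. Genes
#' missing from `records` get rows of `NA`.
#'
#' @param records data.frame with columns `gene_id`, `rpkm_cured`,
#'   `rpkm_infected` and optionally `description`.
#' @param gene_list character vector of gene ids to report.
#' @return data.frame: `gene_id`, `description` (if present), `rpkm_cured`,
#'   `rpkm_infected`, `fold_increase_cured`.
#' @export
defense_report <- function(records, gene_list) {
  stopifnot(all(c("gene_id", "rpkm_cured", "rpkm_infected") %in%
                  names(records)))
  m <- match(gene_list, records$gene_id)
  out <- data.frame(gene_id = gene_list, stringsAsFactors = FALSE)
  if ("description" %in% names(records))
    out$description <- records$description[m]
  out$rpkm_cured <- records$rpkm_cured[m]
  out$rpkm_infected <- records$rpkm_infected[m]
  out$fold_increase_cured <- fold_change(out$rpkm_cured, out$rpkm_infected)
  out
}

#' Bundled defense-gene RPKM levels
#'
#' The published RPKM levels of the host's antiviral immunity genes
#' (CRISPR-Cas adaptation and interference subunits, two CBASS systems,
#' Hachiman) in the virus-cured versus chronically infected strain, with the
#' fold increase as printed. Three rows' printed folds are not reproducible
#' by half-up rounding of the printed RPKM pair (see `printed_consistent`).
#'
#' @return data.frame: `gene_id`, `description`, `rpkm_cured`,
#'   `rpkm_infected`, `printed_fold`, `printed_consistent`.
#' @export
defense_gene_table <- function() {
  path <- system.file("extdata", "defense_gene_rpkm.tsv",
                      package = "crispracq", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
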