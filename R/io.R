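#' Read and write the pipeline's TSV dialects
#'
#' Plain-TSV readers/writers for the tables the pipeline exchanges:
#' long-format labs (`patient`, `week`, `analyte`, `value`), per-patient
#' metadata, feature tables stored features-as-rows x samples-as-columns
#' (the first column holds feature ids; transposed on read to the
#' samples-by-features layout used in R), GWAS summary statistics
#' (`snp chr pos effect_allele other_allele eaf beta se pval`), and a
#' square LD matrix with SNP ids as row and column labels.
#'
#' @param path File path.
#' @name toxbiome-io
NULL

#' @rdname toxbiome-io
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  feats <- raw[[1]]
  m <- t(as.matrix(raw[-1]))
  colnames(m) <- feats
  dplyr::bind_cols(tibble(sample = rownames(m)),
                   as_tibble(m, .name_repair = "minimal"))
}

#' @rdname toxbiome-io
#' @param table Samples-by-features tibble with a `sample` column.
#' @export
write_feature_table <- function(table, path) {
  m <- feature_matrix(table)
  out <- data.frame(feature = colnames(m), t(m), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname toxbiome-io
#' @export
read_gwas_tsv <- function(path) {
  validate_sumstats(utils::read.delim(path, stringsAsFactors = FALSE),
                    path)
}

#' @rdname toxbiome-io
#' @param stats A summary-statistics tibble.
#' @export
write_gwas_tsv <- function(stats, path) {
  utils::write.table(validate_sumstats(stats), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname toxbiome-io
#' @export
read_ld_tsv <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m))) {
    abort("LD matrix must be square with matching SNP labels.")
  }
  m
}

#' @rdname toxbiome-io
#' @param ld A square LD matrix with SNP dimnames.
#' @export
write_ld_tsv <- function(ld, path) {
  out <- data.frame(snp = rownames(ld), ld, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
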