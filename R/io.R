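#' Write genotypes as VCF
#'
#' Minimal VCFv4.2 with GT (unphased, from dosage) and DS fields.
#'
#' @param genotypes a `GenotypeMatrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  panel <- genotypes$panel
  d <- genotypes$dosage
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d))
  body <- apply(cbind(gt, d), 1, function(row) {
    m <- length(row) / 2
    paste(paste0(row[seq_len(m)], ":", row[m + seq_len(m)]),
          collapse = "\t")
  })
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t"),
    paste(panel$chrom, panel$pos, panel$variant_id, panel$ref, panel$alt,
          ".", "PASS", ".", "GT:DS", body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Uses vcfR; returns the DS field when present, otherwise dosage derived
#' from GT.
#'
#' @param path VCF path.
#' @return variants x samples dosage matrix with a `pos` attribute.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col)
      vapply(strsplit(col, "[/|]"), function(a) sum(as.numeric(a)), 0))
  }
  ds <- as.matrix(ds)
  rownames(ds) <- v@fix[, "ID"]
  attr(ds, "pos") <- as.integer(v@fix[, "POS"])
  ds
}

#' Write a feature x sample matrix as TSV
#'
#' @param mat matrix with row and column names.
#' @param path output path.
#' @param id_col name of the first (identifier) column.
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  dt <- data.table::data.table(id = rownames(mat))
  data.table::setnames(dt, "id", id_col)
  out <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a feature x sample TSV back into a matrix
#'
#' @param path TSV path (first column taken as rownames).
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Write CpG counts as a BED-like TSV
#'
#' Columns: chrom, start (0-based), end, then one `meth,total` column per
#' sample.
#'
#' @param cpgs a `CpGTable`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cpg_bed <- function(cpgs, path) {
  cols <- lapply(seq_len(ncol(cpgs$meth)), function(s)
    paste0(cpgs$meth[, s], ",", cpgs$total[, s]))
  dt <- data.table::data.table(chrom = cpgs$chrom, start = cpgs$pos,
                               end = cpgs$pos + 1L)
  for (s in seq_along(cols))
    dt[[colnames(cpgs$meth)[s]]] <- cols[[s]]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read CpG counts from a BED-like TSV
#'
#' @param path TSV written by [write_cpg_bed()].
#' @return a `CpGTable` (chrom, pos, meth, total).
#' @export
read_cpg_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", dec = ".",
                          colClasses = "character")
  dt$start <- as.integer(dt$start)
  dt$end <- as.integer(dt$end)
  samp <- names(dt)[-(1:3)]
  split2 <- function(col) {
    parts <- data.table::tstrsplit(col, ",", fixed = TRUE)
    list(as.integer(parts[[1]]), as.integer(parts[[2]]))
  }
  meth <- total <- matrix(0L, nrow(dt), length(samp),
                          dimnames = list(NULL, samp))
  for (s in seq_along(samp)) {
    sp <- split2(dt[[samp[s]]])
    meth[, s] <- sp[[1]]
    total[, s] <- sp[[2]]
  }
  structure(list(chrom = dt$chrom, pos = dt$start, meth = meth,
                 total = total), class = "CpGTable")
}

#' Write simulation truth as a JSON sidecar
#'
#' @param truth a `SimTruth`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  out <- truth
  class(out) <- NULL
  out$tracts <- NULL  # bulky; kept in memory only
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
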