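# Readers/writers for the tab-separated dialects used across the package:
# header required, UTF-8, '.' for missing values, 1-based coordinates.

na_str <- "."

#' Read a variant table (TSV or VCF)
#'
#' TSV input must carry the VariantRecord columns (`variant_id`, `chrom`,
#' `pos`, `ref`, `alt`, `consequence`, `alt_depth`, `total_depth`, plus
#' optional `af_dbsnp`, `af_gnomad`, `af_exac`, `vertebrate_hits`,
#' `cohort_prevalence`); missing annotation columns stay absent rather than
#' being filled with zeros, and `.` encodes a missing value. VCF input is
#' parsed with the vcfR package: allele depths come from the `AD` FORMAT
#' field of the first sample (ref,alt order), and population frequencies
#' from the INFO keys `AF_DBSNP`, `AF_GNOMAD`, `AF_EXAC` plus
#' `VERT_HITS` when present. `vaf` is (re)computed from the depths.
#'
#' @param path File path.
#' @param format `"auto"` (default; by extension), `"tsv"`, or `"vcf"`.
#' @return Data frame of variant records with 1-based coordinates.
#' @export
read_variant_table <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") return(read_variant_vcf(path))
  v <- read.delim(path, na.strings = na_str, stringsAsFactors = FALSE)
  required <- c("alt_depth", "total_depth")
  missing <- setdiff(required, names(v))
  if (length(missing)) {
    stop("variant TSV lacks required column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(v$total_depth) | v$total_depth <= 0 |
                 v$alt_depth > v$total_depth | v$alt_depth < 0)
  if (length(bad)) {
    stop("malformed variant row at line ", bad[1] + 1L,
         " (depths inconsistent)")
  }
  v$vaf <- v$alt_depth / v$total_depth
  v
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || ncol(ad) < 1) stop("VCF has no AD genotype field")
  parts <- strsplit(ad[, 1], ",", fixed = TRUE)
  ref_d <- vapply(parts, function(x) as.numeric(x[1]), numeric(1))
  alt_d <- vapply(parts, function(x) as.numeric(x[2]), numeric(1))
  info_num <- function(key) {
    x <- vcfR::extract.info(vcf, element = key)
    if (is.null(x)) NULL else suppressWarnings(as.numeric(x))
  }
  out <- data.frame(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    alt_depth = as.integer(alt_d),
    total_depth = as.integer(ref_d + alt_d),
    stringsAsFactors = FALSE
  )
  out$vaf <- out$alt_depth / out$total_depth
  keys <- c(af_dbsnp = "AF_DBSNP", af_gnomad = "AF_GNOMAD", af_exac = "AF_EXAC")
  for (nm in names(keys)) {
    x <- info_num(keys[[nm]])
    if (!is.null(x) && !all(is.na(x))) out[[nm]] <- x
  }
  vh <- info_num("VERT_HITS")
  if (!is.null(vh) && !all(is.na(vh))) out$vertebrate_hits <- as.integer(vh)
  csq <- vcfR::extract.info(vcf, element = "CSQ")
  if (!is.null(csq) && !all(is.na(csq))) out$consequence <- csq
  out
}

#' Write a table in the package TSV dialect
#'
#' Tab-separated, header, no quoting, `.` for missing values.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = na_str, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read segment read counts
#'
#' @param path TSV with columns `segment_id`, `reads_human`, `reads_mouse`.
#' @return Data frame of segment counts.
#' @export
read_segment_counts <- function(path) {
  x <- read.delim(path, na.strings = na_str, stringsAsFactors = FALSE)
  need <- c("segment_id", "reads_human", "reads_mouse")
  if (!all(need %in% names(x))) {
    stop("segment TSV requires columns: ", paste(need, collapse = ", "))
  }
  x
}

#' Read / write an expression matrix
#'
#' TSV with gene identifiers in the first column (`gene_id`) and one column
#' per sample; values are linear-scale, non-negative expression.
#'
#' @param path File path.
#' @return `read_expression_matrix()`: numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path) {
  x <- read.delim(path, na.strings = na_str, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (names(x)[1] != "gene_id") stop("first column must be 'gene_id'")
  if (anyDuplicated(x$gene_id)) stop("duplicate gene identifiers")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
  m
}

#' @param m Numeric matrix with gene rownames.
#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(m, path) {
  write_tsv(data.frame(gene_id = rownames(m), m, check.names = FALSE), path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @param sets Named list of character vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an ortholog map
#'
#' @param path TSV with columns `human_id`, `mouse_id`; one row per
#'   ortholog pair (one-to-many allowed).
#' @return Data frame `human_id`, `mouse_id`.
#' @export
read_ortholog_map <- function(path) {
  x <- read.delim(path, na.strings = na_str, stringsAsFactors = FALSE)
  if (!all(c("human_id", "mouse_id") %in% names(x))) {
    stop("ortholog map requires columns human_id, mouse_id")
  }
  x
}

#' Read score-purity reference pairs
#'
#' @param path TSV with columns `score`, `purity`.
#' @return Data frame usable with [fit_score_purity_curve()].
#' @export
read_reference_pairs <- function(path) {
  x <- read.delim(path, na.strings = na_str, stringsAsFactors = FALSE)
  if (!all(c("score", "purity") %in% names(x))) {
    stop("reference pairs require columns score, purity")
  }
  x
}
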