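# Marker/phenotype I/O, validation, MAF filtering, imputation, alignment.
#
# A marker matrix is a plain numeric matrix, lines in rows (unique rownames
# = line ids), markers in columns (unique colnames = marker ids). Raw
# matrices contain dosages in {0, 1, 2} plus NA; augmented matrices may hold
# any real value in [0, 2]. A trait vector is a named numeric vector with a
# "trait" attribute.

.sep_for <- function(dialect) {
  dialect <- match.arg(dialect, c("csv", "tsv"))
  if (dialect == "csv") "," else "\t"
}

#' Construct a trait vector
#'
#' @param values numeric vector of phenotype values (BLUEs).
#' @param ids character vector of unique line identifiers, same length.
#' @param trait trait name.
#' @return Named numeric vector with attribute `trait`.
#' @export
trait_vector <- function(values, ids, trait = "trait") {
  if (length(values) != length(ids))
    stop("values and ids must have equal length")
  if (anyDuplicated(ids)) stop("duplicate line ids in trait vector")
  values <- as.numeric(values)
  names(values) <- as.character(ids)
  attr(values, "trait") <- trait
  values
}

.trait_name <- function(t) {
  nm <- attr(t, "trait")
  if (is.null(nm)) "trait" else nm
}

# Validates a marker matrix; raw = TRUE additionally enforces {0,1,2} coding.
.check_markers <- function(m, raw = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("marker matrix must be numeric")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("marker matrix requires unique line ids as rownames")
  if (nrow(m) < 2 || ncol(m) < 1)
    stop("marker matrix needs at least 2 lines and 1 marker")
  if (raw) {
    vals <- m[!is.na(m)]
    if (!all(vals %in% c(0, 1, 2)))
      stop("marker dosages must be 0, 1 or 2 (or missing)")
  }
  invisible(m)
}

#' Read a marker matrix from delimited text
#'
#' Expects a header row of marker ids; the first column holds line ids.
#' Cells must be dosages in \{0, 1, 2\}; "NA" or empty cells are missing.
#'
#' @param path path to the file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return Numeric matrix, lines x markers, dimnames set.
#' @export
read_markers <- function(path, dialect = c("csv", "tsv")) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sep_for(match.arg(dialect))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("malformed marker file: need line_id plus markers")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate line ids: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed marker file: non-numeric dosage cells")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  .check_markers(m, raw = TRUE)
  m
}

#' Write a marker matrix to delimited text
#'
#' @param m marker matrix.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_markers <- function(m, path, dialect = c("csv", "tsv")) {
  sep <- .sep_for(match.arg(dialect))
  df <- data.frame(line_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read phenotypes (long format) into a trait vector
#'
#' File columns: `line_id`, `trait`, `value`.
#'
#' @param path path to the file.
#' @param trait trait to extract; may be omitted when the file holds one.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A [trait_vector()].
#' @export
read_phenotypes <- function(path, trait = NULL, dialect = c("csv", "tsv")) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sep_for(match.arg(dialect))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("line_id", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns line_id, trait, value")
  traits <- unique(df$trait)
  if (is.null(trait)) {
    if (length(traits) != 1)
      stop("multiple traits present; specify one of: ",
           paste(traits, collapse = ", "))
    trait <- traits
  }
  if (!trait %in% traits) stop("trait not found in file: ", trait)
  sub <- df[df$trait == trait, ]
  trait_vector(sub$value, sub$line_id, trait)
}

#' Write a trait vector as a long-format phenotype file
#'
#' @param t trait vector.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_phenotypes <- function(t, path, dialect = c("csv", "tsv")) {
  sep <- .sep_for(match.arg(dialect))
  df <- data.frame(line_id = names(t), trait = .trait_name(t),
                   value = as.numeric(t), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read SNP dosages from a VCF
#'
#' Converts GT fields of biallelic sites to ALT-allele dosage: 0/0 -> 0,
#' 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> missing. Multiallelic sites are
#' skipped with a warning.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @return Marker matrix, samples in rows, sites in columns.
#' @export
read_vcf_dosage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    warning(sum(!bi), " multiallelic site(s) skipped")
    vcf <- vcf[bi, ]
  }
  if (nrow(vcf@gt) == 0) stop("no biallelic sites in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alt_count <- function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }
  dos <- apply(gt, c(1, 2), alt_count)
  m <- t(dos)  # samples x sites
  .check_markers(m, raw = TRUE)
  m
}

#' Filter markers by minor allele frequency
#'
#' Per marker the allele frequency is estimated as mean(dosage)/2 over
#' non-missing entries; the marker is kept iff `min(p, 1 - p) >= min_maf`.
#'
#' @param m raw marker matrix (dosages in \{0, 1, 2\}, NA allowed).
#' @param min_maf MAF threshold in `[0, 0.5]`; markers below it are dropped.
#' @return Filtered marker matrix, column order preserved.
#' @export
maf_filter <- function(m, min_maf = 0.05) {
  .check_markers(m, raw = TRUE)
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must be in [0, 0.5]")
  p <- colMeans(m, na.rm = TRUE) / 2
  keep <- pmin(p, 1 - p) >= min_maf
  if (!any(keep)) stop("all markers removed by MAF filter")
  m[, keep, drop = FALSE]
}

#' Impute missing dosages by the marker mean
#'
#' @param m raw marker matrix.
#' @return Matrix with each NA replaced by its column's mean over
#'   non-missing entries.
#' @export
impute_missing <- function(m) {
  .check_markers(m, raw = TRUE)
  if (!anyNA(m)) return(m)
  nmiss <- colSums(!is.na(m))
  if (any(nmiss == 0))
    stop("marker(s) entirely missing: ",
         paste(colnames(m)[nmiss == 0], collapse = ", "))
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- mu[idx[, 2]]
  m
}

#' Align a marker matrix and a trait vector on shared line ids
#'
#' Both are restricted to the intersection of line ids, in the marker
#' matrix's row order; the number of dropped lines is messaged.
#'
#' @param m marker matrix.
#' @param t trait vector.
#' @return `list(markers =, trait =)`, id sequences identical.
#' @export
align_data <- function(m, t) {
  common <- rownames(m)[rownames(m) %in% names(t)]
  if (length(common) == 0) stop("no line ids shared by markers and trait")
  dropped <- (nrow(m) - length(common)) + (length(t) - length(common))
  if (dropped > 0) message(dropped, " line(s) dropped during alignment")
  list(markers = m[common, , drop = FALSE],
       trait = trait_vector(t[common], common, .trait_name(t)))
}
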