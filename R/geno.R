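#' Genotype matrix container
#'
#' Bundles a samples-by-loci matrix of diploid dosage calls with per-locus
#' and per-sample metadata. Calls count copies of the designated alternate
#' allele, so each entry is 0, 1, 2 or `NA` (missing). Because downstream
#' statistics use the folded minor-allele frequency, the choice of which
#' allele is "alternate" cannot change any result.
#'
#' @param calls Integer matrix, samples in rows and loci in columns, entries
#'   in `{0, 1, 2, NA}`. Row and column names are used as sample and locus
#'   identifiers when `sample_ids` / `locus_ids` are not given.
#' @param sample_ids,locus_ids Character vectors of unique identifiers.
#' @param locus_meta Optional data frame with columns `locus_id`,
#'   `reproducibility` (technical-replicate concordance score in \[0, 1\])
#'   and `call_rate`. Missing columns are filled (`call_rate` is always
#'   recomputed from `calls`).
#' @param sample_meta Optional data frame with columns `sample_id`, `site`,
#'   `cohort` (`"adult"` or `"seedling"`), `is_local`, `is_hybrid`.
#'   `n_missing` is always recomputed from `calls`.
#' @return An object of class `"geno"`: a list with elements `calls`,
#'   `locus_meta`, `sample_meta`.
#' @export
geno_matrix <- function(calls, sample_ids = rownames(calls),
                        locus_ids = colnames(calls),
                        locus_meta = NULL, sample_meta = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%d", seq_len(nrow(calls)))
  if (is.null(locus_ids))
    locus_ids <- sprintf("L%d", seq_len(ncol(calls)))
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (length(sample_ids) != nrow(calls))
    stop("length(sample_ids) != nrow(calls)")
  if (length(locus_ids) != ncol(calls))
    stop("length(locus_ids) != ncol(calls)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage code %s at sample '%s', locus '%s'",
                 calls[bad][1], sample_ids[idx[1]], locus_ids[idx[2]]))
  }
  dimnames(calls) <- list(sample_ids, locus_ids)

  lm <- data.frame(locus_id = locus_ids, stringsAsFactors = FALSE)
  if (!is.null(locus_meta)) {
    locus_meta <- as.data.frame(locus_meta)
    if (!"locus_id" %in% names(locus_meta))
      stop("locus_meta needs a 'locus_id' column")
    miss <- setdiff(locus_ids, locus_meta$locus_id)
    if (length(miss))
      stop("locus_meta is missing loci: ", paste(utils::head(miss, 5), collapse = ", "))
    lm <- merge(lm, locus_meta, by = "locus_id", sort = FALSE)
    lm <- lm[match(locus_ids, lm$locus_id), , drop = FALSE]
  }
  if (!"reproducibility" %in% names(lm)) lm$reproducibility <- NA_real_
  lm$call_rate <- colMeans(!is.na(calls))

  sm <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (!"sample_id" %in% names(sample_meta))
      stop("sample_meta needs a 'sample_id' column")
    miss <- setdiff(sample_ids, sample_meta$sample_id)
    if (length(miss))
      stop("sample_meta is missing samples: ", paste(utils::head(miss, 5), collapse = ", "))
    sm <- merge(sm, sample_meta, by = "sample_id", sort = FALSE)
    sm <- sm[match(sample_ids, sm$sample_id), , drop = FALSE]
  }
  for (col in c("site", "cohort")) if (!col %in% names(sm)) sm[[col]] <- NA_character_
  for (col in c("is_local", "is_hybrid")) if (!col %in% names(sm)) sm[[col]] <- NA
  sm$n_missing <- as.integer(rowSums(is.na(calls)))
  rownames(lm) <- NULL
  rownames(sm) <- NULL

  structure(list(calls = calls, locus_meta = lm, sample_meta = sm),
            class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf("<geno> %d samples x %d loci (%.1f%% missing calls)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  sites <- unique(stats::na.omit(x$sample_meta$site))
  if (length(sites))
    cat("  sites: ", paste(sites, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$calls)

#' Sample and locus identifiers of a genotype matrix
#' @param g A `geno` object.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(g) rownames(g$calls)

#' @rdname sample_ids
#' @export
locus_ids <- function(g) colnames(g$calls)

#' Subset a genotype matrix by sample and/or locus identifiers
#'
#' Metadata rows are subset consistently; `n_missing` and `call_rate`
#' are recomputed for the new extent.
#'
#' @param g A `geno` object.
#' @param samples,loci Character vectors of ids (default: keep all).
#' @return A `geno` object.
#' @export
subset_geno <- function(g, samples = NULL, loci = NULL) {
  stopifnot(inherits(g, "geno"))
  if (is.null(samples)) samples <- sample_ids(g)
  if (is.null(loci)) loci <- locus_ids(g)
  missing_s <- setdiff(samples, sample_ids(g))
  if (length(missing_s))
    stop("unknown sample ids: ", paste(utils::head(missing_s, 5), collapse = ", "))
  missing_l <- setdiff(loci, locus_ids(g))
  if (length(missing_l))
    stop("unknown locus ids: ", paste(utils::head(missing_l, 5), collapse = ", "))
  lm <- g$locus_meta[match(loci, g$locus_meta$locus_id), , drop = FALSE]
  lm$call_rate <- NULL
  sm <- g$sample_meta[match(samples, g$sample_meta$sample_id), , drop = FALSE]
  sm$n_missing <- NULL
  geno_matrix(g$calls[samples, loci, drop = FALSE],
              locus_meta = lm, sample_meta = sm)
}

# dosage codes accepted in text formats
.parse_dosage <- function(x, where) {
  x <- trimws(x)
  x[x %in% c("NA", "na", "-", "")] <- NA
  out <- suppressWarnings(as.integer(x))
  bad <- which(!is.na(x) & (is.na(out) | !(out %in% 0:2)))
  if (length(bad))
    stop(sprintf("unknown dosage token '%s' at %s", x[bad[1]], where[bad[1]]))
  out
}

#' Read SNP genotypes from standard text formats
#'
#' Supported formats:
#' \describe{
#'   \item{`matrix_csv`}{Plain dosage table, one row per sample; first
#'     column holds sample ids, remaining column names are locus ids.
#'     Dosages are `0/1/2`, with `NA`, `-` or an empty field for missing.}
#'   \item{`dart_csv`}{One row per locus: columns `locus_id`,
#'     `reproducibility`, `call_rate`, then one dosage column per sample.
#'     This is the package's documented dosage dialect for DArT-style SNP
#'     tables (the two-row raw DArT format is not supported).}
#'   \item{`vcf`}{VCF with GT fields. Only biallelic SNP records are kept;
#'     the number of rejected records is reported via a message and the
#'     `n_rejected` attribute.}
#' }
#'
#' @param path File path.
#' @param format One of `"matrix_csv"`, `"dart_csv"`, `"vcf"`.
#' @param sample_meta Optional data frame (or path to a tab-separated file)
#'   with per-sample metadata, joined by `sample_id`.
#' @return A `geno` object; for VCF input the attribute `n_rejected` counts
#'   multi-allelic or non-SNP records that were dropped.
#' @export
read_genotypes <- function(path, format = c("matrix_csv", "dart_csv", "vcf"),
                           sample_meta = NULL) {
  format <- match.arg(format)
  if (is.character(sample_meta) && length(sample_meta) == 1)
    sample_meta <- utils::read.delim(sample_meta, stringsAsFactors = FALSE)

  if (format == "matrix_csv") {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
    sid <- tab[[1]]
    loci <- names(tab)[-1]
    calls <- matrix(NA_integer_, nrow(tab), length(loci))
    for (j in seq_along(loci)) {
      calls[, j] <- .parse_dosage(
        tab[[j + 1]],
        sprintf("row %d, column '%s'", seq_len(nrow(tab)), loci[j]))
    }
    dimnames(calls) <- list(sid, loci)
    return(geno_matrix(calls, sample_meta = sample_meta))
  }

  if (format == "dart_csv") {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("locus_id", "reproducibility", "call_rate")
    if (!all(need %in% names(tab)))
      stop("dart_csv requires columns: ", paste(need, collapse = ", "))
    sid <- setdiff(names(tab), need)
    calls <- matrix(NA_integer_, length(sid), nrow(tab))
    for (i in seq_along(sid)) {
      calls[i, ] <- .parse_dosage(
        tab[[sid[i]]],
        sprintf("locus row %d, sample '%s'", seq_len(nrow(tab)), sid[i]))
    }
    dimnames(calls) <- list(sid, tab$locus_id)
    lm <- data.frame(locus_id = tab$locus_id,
                     reproducibility = as.numeric(tab$reproducibility),
                     stringsAsFactors = FALSE)
    return(geno_matrix(calls, locus_meta = lm, sample_meta = sample_meta))
  }

  # vcf
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_rejected <- sum(!keep)
  if (n_rejected)
    message(n_rejected, " multi-allelic or non-SNP record(s) rejected")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  ids <- fix[keep, "ID"]
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[no_id]
  # dosage = number of ALT alleles in the GT field
  dose <- function(x) {
    al <- strsplit(gsub("|", "/", x, fixed = TRUE), "/", fixed = TRUE)
    vapply(al, function(a) {
      if (length(a) == 0 || any(is.na(a)) || any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  calls <- matrix(NA_integer_, ncol(gt), nrow(gt),
                  dimnames = list(colnames(gt), ids))
  for (s in seq_len(ncol(gt))) calls[s, ] <- dose(gt[, s])
  g <- geno_matrix(calls, sample_meta = sample_meta)
  attr(g, "n_rejected") <- n_rejected
  g
}

#' Write genotypes to a dosage table
#'
#' @param g A `geno` object.
#' @param path Output file path.
#' @param format `"matrix_csv"` or `"dart_csv"` (see [read_genotypes()]).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("matrix_csv", "dart_csv")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "geno"))
  if (format == "matrix_csv") {
    tab <- data.frame(sample_id = sample_ids(g),
                      as.data.frame(g$calls, check.names = FALSE),
                      check.names = FALSE)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    tab <- data.frame(locus_id = locus_ids(g),
                      reproducibility = g$locus_meta$reproducibility,
                      call_rate = g$locus_meta$call_rate,
                      as.data.frame(t(g$calls), check.names = FALSE),
                      check.names = FALSE)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "NA")
  }
  invisible(path)
}
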