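#' Filter SNP loci on quality criteria
#'
#' Applies, in order, (i) a technical-reproducibility filter (keep loci with
#' score strictly greater than `reproducibility_min`), (ii) a missingness
#' filter (keep loci whose missing-call fraction is less than or equal to
#' `missing_max`; loci missing in more than that fraction of samples are
#' excluded), and (iii) optionally a complete-data filter (keep only loci
#' with zero missing calls). Rules with a `NULL` threshold are skipped.
#' Locus order is preserved.
#'
#' @param g A `geno` object.
#' @param reproducibility_min Reproducibility threshold (strict `>`), or
#'   `NULL` to skip. Default 0.96.
#' @param missing_max Maximum tolerated missing fraction per locus
#'   (inclusive), or `NULL` to skip. Default 0.20.
#' @param require_complete If `TRUE`, additionally drop every locus with any
#'   missing call.
#' @return A filtered `geno` with a per-rule report available via
#'   [filter_report()]. If every locus is removed a warning is raised and an
#'   empty matrix returned.
#' @export
filter_loci <- function(g, reproducibility_min = 0.96, missing_max = 0.20,
                        require_complete = FALSE) {
  stopifnot(inherits(g, "geno"))
  if (!is.null(reproducibility_min))
    stopifnot(reproducibility_min >= 0, reproducibility_min <= 1)
  if (!is.null(missing_max))
    stopifnot(missing_max >= 0, missing_max <= 1)

  keep <- rep(TRUE, ncol(g$calls))
  report <- data.frame(rule = character(0), removed = integer(0),
                       retained = integer(0), stringsAsFactors = FALSE)
  note <- function(rule, newkeep) {
    report <<- rbind(report, data.frame(
      rule = rule, removed = sum(keep & !newkeep),
      retained = sum(newkeep), stringsAsFactors = FALSE))
    newkeep
  }
  if (!is.null(reproducibility_min)) {
    rep_ok <- !is.na(g$locus_meta$reproducibility) &
      g$locus_meta$reproducibility > reproducibility_min
    keep <- note(sprintf("reproducibility > %g", reproducibility_min),
                 keep & rep_ok)
  }
  if (!is.null(missing_max)) {
    miss_frac <- colMeans(is.na(g$calls))
    keep <- note(sprintf("missing fraction <= %g", missing_max),
                 keep & miss_frac <= missing_max)
  }
  if (require_complete) {
    keep <- note("complete data", keep & colSums(is.na(g$calls)) == 0)
  }
  if (!any(keep))
    warning("all loci removed by filters; returning empty matrix")
  out <- subset_geno(g, loci = locus_ids(g)[keep])
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the per-rule report attached by [filter_loci()]
#' @param g A filtered `geno` object.
#' @return Data frame with columns `rule`, `removed`, `retained`.
#' @export
filter_report <- function(g) attr(g, "filter_report")

#' Write a filter report as tab-separated text
#' @param g A filtered `geno` object (or a report data frame).
#' @param path Output path.
#' @export
write_filter_report <- function(g, path) {
  rep <- if (is.data.frame(g)) g else filter_report(g)
  utils::write.table(rep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove samples with excessive missing data
#'
#' Samples whose fraction of missing calls is strictly greater than
#' `max_missing_fraction` are dropped; removals are reported via the
#' `removed_samples` attribute and a message.
#'
#' @param g A `geno` object.
#' @param max_missing_fraction Threshold in \[0, 1\]; default 0.5.
#' @return A `geno` object.
#' @export
remove_high_missing_samples <- function(g, max_missing_fraction = 0.5) {
  stopifnot(inherits(g, "geno"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(g$calls))
  drop <- sample_ids(g)[frac > max_missing_fraction]
  if (length(drop))
    message("removed ", length(drop), " sample(s) with missing fraction > ",
            max_missing_fraction, ": ", paste(drop, collapse = ", "))
  out <- subset_geno(g, samples = setdiff(sample_ids(g), drop))
  attr(out, "removed_samples") <- drop
  out
}

#' Alternate-allele frequencies over a sample subset
#'
#' Frequencies are computed over non-missing calls only:
#' `freq = sum(dosage) / (2 * n_called)`. Loci with no non-missing call in
#' the subset get `NA` and are flagged via the `undefined` attribute.
#'
#' @param g A `geno` object.
#' @param samples Character vector of sample ids (default: all).
#' @return Named numeric vector of alternate-allele frequencies with
#'   attributes `n_called` (samples with data per locus) and `undefined`
#'   (locus ids with no data).
#' @export
allele_freqs <- function(g, samples = NULL) {
  stopifnot(inherits(g, "geno"))
  if (is.null(samples)) samples <- sample_ids(g)
  if (length(samples) == 0) stop("empty sample subset")
  x <- g$calls[samples, , drop = FALSE]
  n_called <- colSums(!is.na(x))
  freq <- colSums(x, na.rm = TRUE) / (2 * n_called)
  freq[n_called == 0] <- NA_real_
  attr(freq, "n_called") <- n_called
  attr(freq, "undefined") <- locus_ids(g)[n_called == 0]
  freq
}

#' Common loci in a reference sample set
#'
#' A locus is "common" when its minor allele frequency, computed on the
#' reference subset, is strictly greater than `maf_min`. The reference set
#' is typically the condemned population (or its adult cohort); capture and
#' retention downstream are measured against this set.
#'
#' @param g A `geno` object.
#' @param reference Sample ids defining the reference set (default: all).
#' @param maf_min Minor-allele-frequency threshold (strict `>`), e.g. 0.02
#'   or 0.03.
#' @return Character vector of locus ids.
#' @export
common_loci <- function(g, reference = NULL, maf_min = 0.02) {
  freq <- allele_freqs(g, reference)
  maf <- pmin(freq, 1 - freq)
  locus_ids(g)[!is.na(maf) & maf > maf_min]
}
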