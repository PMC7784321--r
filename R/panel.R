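#' Construct a phased haplotype panel
#'
#' A `haplotype_panel` is the substrate of every statistic in the package: a
#' haplotypes-by-sites matrix of phased biallelic alleles together with site
#' coordinates and a sample-to-population map.  Haplotype rows `2i - 1` and
#' `2i` belong to diploid individual `i` (in the order of `sample_ids`), so
#' phase is preserved across all operations.
#'
#' @param chrom Character vector of chromosome labels, one per site.  Sites
#'   of one chromosome must be contiguous.
#' @param positions Integer vector of 1-based bp coordinates, strictly
#'   increasing within each chromosome.
#' @param ref,alt Single-base reference / alternate alleles per site.
#' @param hap Integer matrix, haplotypes x sites, entries in `{0, 1, NA}`
#'   (0 = ref, 1 = alt, NA = missing).
#' @param sample_ids Character vector of sample names; `nrow(hap)` must be
#'   `2 * length(sample_ids)`.
#' @param populations Character vector of population labels, one per sample.
#'
#' @return An object of class `haplotype_panel`.
#' @export
#' @examples
#' p <- haplotype_panel(
#'   chrom = c("chr1", "chr1"), positions = c(100L, 200L),
#'   ref = c("A", "C"), alt = c("G", "T"),
#'   hap = matrix(c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L), nrow = 4),
#'   sample_ids = c("s1", "s2"), populations = c("popA", "popB")
#' )
#' p
haplotype_panel <- function(chrom, positions, ref, alt, hap, sample_ids,
                            populations) {
  if (!is.matrix(hap)) hap <- matrix(hap, ncol = length(positions))
  storage.mode(hap) <- "integer"
  n_sites <- length(positions)
  n_samples <- length(sample_ids)
  stopifnot(
    length(chrom) == n_sites, length(ref) == n_sites, length(alt) == n_sites,
    ncol(hap) == n_sites, nrow(hap) == 2L * n_samples,
    length(populations) == n_samples
  )
  ok <- hap %in% c(0L, 1L, NA_integer_)
  if (!all(ok)) {
    abort("haplotype entries must be 0, 1 or NA")
  }
  rle_chrom <- rle(as.character(chrom))
  if (anyDuplicated(rle_chrom$values)) {
    abort("sites of one chromosome must be contiguous")
  }
  for (cc in rle_chrom$values) {
    p <- positions[chrom == cc]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      abort(sprintf("positions not strictly increasing on %s", cc))
    }
  }
  structure(
    list(
      chrom = as.character(chrom),
      positions = as.integer(positions),
      ref = as.character(ref),
      alt = as.character(alt),
      hap = hap,
      sample_ids = as.character(sample_ids),
      populations = setNames(as.character(populations),
                             as.character(sample_ids))
    ),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  pops <- table(x$populations)
  cat(sprintf(
    "<haplotype_panel> %d sites on %s | %d samples (%d haplotypes)\n",
    n_sites(x), paste(unique(x$chrom), collapse = ","),
    n_samples(x), nrow(x$hap)
  ))
  cat("  populations:",
      paste(sprintf("%s=%d", names(pops), pops), collapse = ", "), "\n")
  miss <- mean(is.na(x$hap))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Panel dimensions
#'
#' @param panel A [haplotype_panel()].
#' @return Number of sites / samples.
#' @export
n_sites <- function(panel) length(panel$positions)

#' @rdname n_sites
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' Site coordinate table of a panel
#'
#' @param panel A [haplotype_panel()].
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
site_table <- function(panel) {
  tibble(chrom = panel$chrom, pos = panel$positions,
         ref = panel$ref, alt = panel$alt)
}

#' Subset a panel by site index or by population
#'
#' @param panel A [haplotype_panel()].
#' @param idx Integer or logical site index.
#' @return A new `haplotype_panel`.
#' @export
subset_sites <- function(panel, idx) {
  haplotype_panel(
    chrom = panel$chrom[idx], positions = panel$positions[idx],
    ref = panel$ref[idx], alt = panel$alt[idx],
    hap = panel$hap[, idx, drop = FALSE],
    sample_ids = panel$sample_ids,
    populations = unname(panel$populations)
  )
}

#' @rdname subset_sites
#' @param pop Population label(s) to keep.
#' @export
panel_pop <- function(panel, pop) {
  unknown <- setdiff(pop, unique(panel$populations))
  if (length(unknown)) {
    abort(sprintf("unknown population label(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  keep <- which(panel$populations %in% pop)
  hap_rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  haplotype_panel(
    chrom = panel$chrom, positions = panel$positions,
    ref = panel$ref, alt = panel$alt,
    hap = panel$hap[hap_rows, , drop = FALSE],
    sample_ids = panel$sample_ids[keep],
    populations = unname(panel$populations[keep])
  )
}

# haplotype row indices of the given samples (or all)
hap_rows_of <- function(panel, samples = NULL) {
  idx <- if (is.null(samples)) seq_len(n_samples(panel)) else
    match(samples, panel$sample_ids)
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Per-site alternate-allele frequency
#'
#' Frequencies are computed over non-missing haplotypes, pooled or within
#' one population.
#'
#' @param panel A [haplotype_panel()].
#' @param pop Optional population label; default pooled over all samples.
#' @return Numeric vector of alt-allele frequencies (NaN where no
#'   non-missing haplotype exists).
#' @export
site_freq <- function(panel, pop = NULL) {
  h <- panel$hap
  if (!is.null(pop)) {
    keep <- which(panel$populations %in% pop)
    if (!length(keep)) abort(sprintf("unknown population label: %s", pop))
    h <- h[as.vector(rbind(2L * keep - 1L, 2L * keep)), , drop = FALSE]
  }
  colMeans(h, na.rm = TRUE)
}

# per-site count of non-missing haplotypes
site_n <- function(panel, pop = NULL) {
  h <- panel$hap
  if (!is.null(pop)) {
    keep <- which(panel$populations %in% pop)
    h <- h[as.vector(rbind(2L * keep - 1L, 2L * keep)), , drop = FALSE]
  }
  colSums(!is.na(h))
}

# require a complete (no missing entry) panel for the EHH family
assert_complete <- function(panel, what = "this operation") {
  if (anyNA(panel$hap)) {
    abort(sprintf(
      "%s requires a complete panel; run naive_impute() or filter first",
      what
    ))
  }
  invisible(panel)
}
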