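new_filter_report <- function(rule, mask, n_all_missing = 0L) {
  structure(
    list(
      rule = rule,
      n_sites_in = length(mask),
      n_sites_removed = sum(mask),
      n_sites_kept = sum(!mask),
      n_all_missing = n_all_missing,
      removed_mask = mask
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> rule=%s: %d sites in, %d removed, %d kept\n",
              x$rule, x$n_sites_in, x$n_sites_removed, x$n_sites_kept))
  if (x$n_all_missing > 0) {
    cat(sprintf("  (%d site(s) removed for being entirely missing)\n",
                x$n_all_missing))
  }
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  tibble(rule = x$rule, n_sites_in = x$n_sites_in,
         n_sites_removed = x$n_sites_removed, n_sites_kept = x$n_sites_kept,
         n_all_missing = x$n_all_missing)
}

#' Remove sites with excess missing data
#'
#' Drops every site whose fraction of missing haplotype entries, pooled
#' across all samples and populations, is strictly greater than
#' `max_missing_frac`; a site at exactly the threshold is kept.
#'
#' @param panel A [haplotype_panel()].
#' @param max_missing_frac Maximum tolerated missing fraction (default 0.20).
#' @return A list with elements `panel` (filtered) and `report`
#'   (a `filter_report`).
#' @export
filter_missing_sites <- function(panel, max_missing_frac = 0.20) {
  stopifnot(max_missing_frac >= 0, max_missing_frac < 1)
  frac <- colMeans(is.na(panel$hap))
  removed <- frac > max_missing_frac
  list(panel = subset_sites(panel, !removed),
       report = new_filter_report("missingness", removed))
}

#' Remove sites below a minor-allele-frequency threshold
#'
#' MAF is computed over non-missing haplotypes pooled across populations;
#' sites with `MAF < min_maf` are removed (a site at exactly `min_maf` is
#' kept).  Sites with all entries missing are removed and counted
#' separately in the report.
#'
#' @param panel A [haplotype_panel()].
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @return A list with elements `panel` and `report`.
#' @export
filter_maf <- function(panel, min_maf = 0.01) {
  if (n_sites(panel) == 0L) abort("filter_maf() needs a nonempty panel")
  p <- site_freq(panel)
  all_missing <- is.nan(p)
  maf <- pmin(p, 1 - p)
  removed <- all_missing | maf < min_maf
  list(panel = subset_sites(panel, !removed),
       report = new_filter_report("maf", removed,
                                  n_all_missing = sum(all_missing)))
}

#' Naive frequency-based imputation of missing haplotype entries
#'
#' Each missing entry is drawn as a Bernoulli variable with the site's
#' alt-allele frequency within the individual's own population (falling
#' back to the pooled frequency when the population is entirely missing at
#' the site, and to 0 when the site is missing everywhere).  This is a
#' deliberately simple stand-in imputer for pipelines whose upstream data
#' were statistically phased and imputed; it is deterministic given `seed`.
#'
#' @param panel A [haplotype_panel()].
#' @param seed Integer seed.
#' @return A complete [haplotype_panel()] (no missing entries).
#' @export
naive_impute <- function(panel, seed) {
  if (!anyNA(panel$hap)) return(panel)
  hap <- panel$hap
  pooled <- site_freq(panel)
  pop_levels <- unique(panel$populations)
  pop_freq <- vapply(pop_levels, function(pp) site_freq(panel, pp),
                     numeric(n_sites(panel)))
  if (n_sites(panel) == 1L) pop_freq <- matrix(pop_freq, nrow = 1L)
  colnames(pop_freq) <- pop_levels
  pop_of_hap <- rep(unname(panel$populations), each = 2L)

  n_unresolved <- 0L
  withr::with_seed(seed, {
    miss <- which(is.na(hap), arr.ind = TRUE)
    f <- pop_freq[cbind(miss[, 2], match(pop_of_hap[miss[, 1]], pop_levels))]
    fallback <- is.nan(f)
    f[fallback] <- pooled[miss[fallback, 2]]
    dead <- is.nan(f)
    n_unresolved <- sum(dead)
    f[dead] <- 0
    hap[miss] <- rbinom(nrow(miss), 1L, f)
  })
  if (n_unresolved > 0) {
    inform(sprintf(
      "%d entr(ies) at fully missing sites imputed as reference", n_unresolved
    ))
  }
  haplotype_panel(panel$chrom, panel$positions, panel$ref, panel$alt, hap,
                  panel$sample_ids, unname(panel$populations))
}

#' Exclusive and shared polymorphic-site counts per population
#'
#' A site is polymorphic in population P when both alleles are observed
#' among P's non-missing haplotypes.  `exclusive` counts sites polymorphic
#' in P and in no other listed population; `shared` counts sites
#' polymorphic in both members of each population pair.
#'
#' @param panel A [haplotype_panel()].
#' @param pops Population labels to summarize (default: all in the panel).
#' @return A list of two tibbles: `exclusive` (`pop`, `n_polymorphic`,
#'   `n_exclusive`) and `shared` (`pop_a`, `pop_b`, `n_shared`).
#' @export
snp_sharing_summary <- function(panel, pops = NULL) {
  pops <- pops %||% unique(unname(panel$populations))
  unknown <- setdiff(pops, unique(panel$populations))
  if (length(unknown)) {
    abort(sprintf("unknown population label(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (length(pops) < 2L) abort("need at least two populations")
  poly <- vapply(pops, function(pp) {
    f <- site_freq(panel, pp)
    !is.nan(f) & f > 0 & f < 1
  }, logical(n_sites(panel)))
  if (n_sites(panel) == 1L) poly <- matrix(poly, nrow = 1L)
  n_poly_pops <- rowSums(poly)
  exclusive <- tibble(
    pop = pops,
    n_polymorphic = colSums(poly),
    n_exclusive = vapply(seq_along(pops), function(j) {
      sum(poly[, j] & n_poly_pops == 1L)
    }, integer(1))
  )
  pairs <- combn(pops, 2L)
  shared <- tibble(
    pop_a = pairs[1, ], pop_b = pairs[2, ],
    n_shared = vapply(seq_len(ncol(pairs)), function(k) {
      sum(poly[, match(pairs[1, k], pops)] & poly[, match(pairs[2, k], pops)])
    }, integer(1))
  )
  list(exclusive = exclusive, shared = shared)
}

#' Per-individual heterozygosity
#'
#' Proportion of sites at which an individual carries one ref and one alt
#' allele; sites with any missing entry for that individual are excluded
#' from its denominator.
#'
#' @param panel A [haplotype_panel()].
#' @return A tibble with columns `sample_id`, `population`, `n_callable`,
#'   `n_het`, `heterozygosity` (NA for individuals with no callable site).
#' @export
individual_heterozygosity <- function(panel) {
  idx <- seq_len(n_samples(panel))
  h1 <- panel$hap[2L * idx - 1L, , drop = FALSE]
  h2 <- panel$hap[2L * idx, , drop = FALSE]
  callable <- !is.na(h1) & !is.na(h2)
  het <- callable & (h1 != h2)
  n_callable <- rowSums(callable)
  tibble(
    sample_id = panel$sample_ids,
    population = unname(panel$populations),
    n_callable = n_callable,
    n_het = rowSums(het),
    heterozygosity = ifelse(n_callable > 0, rowSums(het) / n_callable,
                            NA_real_)
  )
}
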