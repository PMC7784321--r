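#' Tile a chromosome with consecutive non-overlapping windows
#'
#' Windows are 1-based inclusive `[start, end]` intervals of `size` bp;
#' the final window is truncated to the chromosome end and flagged
#' `partial`.
#'
#' @param chrom_length Chromosome length in bp.
#' @param size Window size in bp (default 30000).
#' @param chrom Chromosome label for the output.
#' @return A tibble with columns `chrom`, `start`, `end`, `width`,
#'   `partial`.
#' @export
#' @examples
#' make_windows(1e5, 3e4)
make_windows <- function(chrom_length, size = 30000, chrom = "chr1") {
  stopifnot(chrom_length >= 1, size >= 1)
  n <- ceiling(chrom_length / size)
  start <- (seq_len(n) - 1L) * size + 1L
  end <- pmin(seq_len(n) * size, chrom_length)
  tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
         width = as.integer(end - start + 1L),
         partial = end - start + 1L < size)
}

#' @rdname make_windows
#' @param chrom_lengths Named vector of chromosome lengths.
#' @export
make_window_grid <- function(chrom_lengths, size = 30000) {
  purrr::map_dfr(names(chrom_lengths), function(cc) {
    make_windows(chrom_lengths[[cc]], size = size, chrom = cc)
  })
}

# index of the grid window containing each site (NA outside the grid)
window_of_site <- function(panel, grid) {
  out <- rep(NA_integer_, n_sites(panel))
  for (cc in unique(panel$chrom)) {
    g <- which(grid$chrom == cc)
    if (!length(g)) next
    s <- which(panel$chrom == cc)
    j <- findInterval(panel$positions[s], grid$start[g])
    ok <- j >= 1L & panel$positions[s] <= grid$end[g][pmax(j, 1L)]
    out[s[ok]] <- g[j[ok]]
  }
  out
}

harmonic_a <- function(n) {
  vapply(n, function(k) if (k < 2) NA_real_ else sum(1 / seq_len(k - 1)),
         numeric(1))
}

#' Windowed Watterson theta with per-site sample-size correction
#'
#' For each window, `theta_w = sum_s 1/a(n_s) / L` over segregating sites
#' `s` in the window, where `n_s` is the site's non-missing haplotype count
#' and `a(n) = sum_{i=1}^{n-1} 1/i`.  Sites monomorphic among non-missing
#' haplotypes contribute 0.  `L` is the full window length unless a
#' `callable_length` vector is supplied.
#'
#' @param panel A [haplotype_panel()].
#' @param grid A window grid from [make_windows()] / [make_window_grid()].
#' @param callable_length Optional per-window callable length (bp).
#' @return `grid` with added columns `S` (segregating sites), `L` and
#'   `theta_w` (per bp; NA where `L` is 0).
#' @export
watterson_theta_windows <- function(panel, grid, callable_length = NULL) {
  p <- site_freq(panel)
  n <- site_n(panel)
  seg <- !is.nan(p) & p > 0 & p < 1 & n >= 2L
  contrib <- ifelse(seg, 1 / harmonic_a(pmax(n, 2L)), 0)
  w <- window_of_site(panel, grid)
  S <- tabulate(w[seg], nbins = nrow(grid))
  theta_sum <- vapply(seq_len(nrow(grid)), function(j) {
    sum(contrib[which(w == j)])
  }, numeric(1))
  L <- callable_length %||% grid$width
  grid %>%
    mutate(S = S, L = as.numeric(L),
           theta_w = ifelse(L > 0, theta_sum / L, NA_real_))
}

# per-site Hudson numerator/denominator between two populations
hudson_site_terms <- function(panel, pop_a, pop_b) {
  p1 <- site_freq(panel, pop_a); n1 <- site_n(panel, pop_a)
  p2 <- site_freq(panel, pop_b); n2 <- site_n(panel, pop_b)
  ok <- n1 >= 2L & n2 >= 2L
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- ok & !is.nan(den) & den > 0
  list(num = num, den = den, ok = ok)
}

wc_site_terms <- function(panel, pop_a, pop_b) {
  # Weir-Cockerham variance components on haploid allele counts (r = 2)
  p1 <- site_freq(panel, pop_a); n1 <- site_n(panel, pop_a)
  p2 <- site_freq(panel, pop_b); n2 <- site_n(panel, pop_b)
  ok <- n1 >= 2L & n2 >= 2L
  nbar <- (n1 + n2) / 2
  nc <- (2 * nbar - (n1^2 + n2^2) / (2 * nbar))
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
  ok <- ok & !is.nan(pbar) & (pbar > 0 & pbar < 1)
  list(num = a, den = a + b, ok = ok)
}

#' Windowed F_ST between two populations
#'
#' Hudson's estimator as a ratio of sums over the sites of each window:
#' `num_s = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `den_s = p1(1-p2) + p2(1-p1)`, with per-site non-missing haplotype
#' counts.  Sites with zero denominator or fewer than 2 haplotypes in
#' either population are excluded.  A Weir-Cockerham variant is available
#' via `estimator = "wc"`.
#'
#' @param panel A [haplotype_panel()].
#' @param pop_a,pop_b Population labels.
#' @param grid Window grid.
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return `grid` with added columns `n_sites_used` and `fst` (NA for
#'   windows with no eligible site).
#' @export
hudson_fst_windows <- function(panel, pop_a, pop_b, grid,
                               estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  terms <- if (estimator == "hudson") hudson_site_terms(panel, pop_a, pop_b)
           else wc_site_terms(panel, pop_a, pop_b)
  w <- window_of_site(panel, grid)
  use <- terms$ok & !is.na(w)
  out <- grid %>% mutate(n_sites_used = 0L, fst = NA_real_)
  if (any(use)) {
    num <- vapply(split(terms$num[use], w[use]), sum, numeric(1))
    den <- vapply(split(terms$den[use], w[use]), sum, numeric(1))
    cnt <- table(w[use])
    j <- as.integer(names(num))
    out$n_sites_used[j] <- as.integer(cnt)
    out$fst[j] <- num / den
  }
  out
}

#' Genome-wide F_ST (ratio of sums over all sites)
#'
#' @inheritParams hudson_fst_windows
#' @return A single numeric F_ST estimate.
#' @export
hudson_fst <- function(panel, pop_a, pop_b, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  terms <- if (estimator == "hudson") hudson_site_terms(panel, pop_a, pop_b)
           else wc_site_terms(panel, pop_a, pop_b)
  if (!any(terms$ok)) return(NA_real_)
  sum(terms$num[terms$ok]) / sum(terms$den[terms$ok])
}
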