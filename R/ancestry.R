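#' Read a local-ancestry dosage table
#'
#' Consumes a whitespace-delimited numeric matrix of expected donor-allele
#' dosages (sites x individuals, entries in `[0, 2]`) together with a
#' site-info sidecar TSV (`chrom`, `pos`, one row per matrix row), the
#' layout produced by two-way local-ancestry inference tools and by this
#' package's simulator truth export.
#'
#' @param path Path to the dosage matrix.
#' @param sites_path Path to the site-info TSV.
#' @param sample_ids Optional sample names (default: matrix column names,
#'   else `ind1..indK`).
#' @return A tidy `dosage_table` tibble with columns `chrom`, `pos`,
#'   `sample_id`, `dosage`.
#' @export
read_dosage_table <- function(path, sites_path, sample_ids = NULL) {
  m <- as.matrix(read.table(path, header = TRUE, check.names = FALSE))
  sites <- read.table(sites_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  if (nrow(m) != nrow(sites)) {
    abort(sprintf("dosage matrix has %d rows but site info has %d",
                  nrow(m), nrow(sites)))
  }
  bad <- which(is.na(m) | m < 0 | m > 2, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("dosage entry outside [0, 2] at row %d, column %d",
                  bad[1, 1], bad[1, 2]))
  }
  ids <- sample_ids %||% colnames(m) %||% paste0("ind", seq_len(ncol(m)))
  as_dosage_table(m, sites$chrom, sites$pos, ids)
}

as_dosage_table <- function(m, chrom, pos, sample_ids) {
  d <- tibble(
    chrom = rep(as.character(chrom), times = ncol(m)),
    pos = rep(as.integer(pos), times = ncol(m)),
    sample_id = rep(as.character(sample_ids), each = nrow(m)),
    dosage = as.vector(m)
  ) %>% arrange(sample_id, chrom, pos)
  class(d) <- c("dosage_table", class(d))
  d
}

#' Write a dosage table (matrix + site-info sidecar)
#'
#' @param dosages A `dosage_table` tibble.
#' @param path Output path for the matrix.
#' @param sites_path Output path for the site-info TSV.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(dosages, path, sites_path) {
  wide <- dosages %>%
    tidyr::pivot_wider(names_from = sample_id, values_from = dosage) %>%
    arrange(chrom, pos)
  write.table(wide %>% select(-chrom, -pos), path, sep = " ",
              quote = FALSE, row.names = FALSE)
  write.table(wide %>% select(chrom, pos), sites_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean donor-ancestry fraction per window
#'
#' The window value is the mean of `dosage / 2` over all sites in the
#' window and all individuals; windows containing no site are NA.
#'
#' @param dosages A `dosage_table` tibble.
#' @param grid Window grid.
#' @return `grid` with added columns `n_sites` and `donor_fraction`.
#' @export
window_donor_fraction <- function(dosages, grid) {
  w <- window_of_pos(dosages$chrom, dosages$pos, grid)
  agg <- dosages %>%
    mutate(window = w) %>%
    filter(!is.na(window)) %>%
    group_by(window) %>%
    summarise(n_sites = n_distinct(pos),
              donor_fraction = mean(dosage) / 2, .groups = "drop")
  grid %>%
    mutate(window = row_number()) %>%
    left_join(agg, by = "window") %>%
    mutate(n_sites = ifelse(is.na(n_sites), 0L, n_sites)) %>%
    select(-window)
}

#' Donor-ancestry fraction per individual and chromosome
#'
#' @param dosages A `dosage_table` tibble.
#' @param chroms Optional chromosome labels to report (default: those
#'   present; absent requested chromosomes yield NA).
#' @return A tibble with columns `sample_id`, `chrom`, `n_sites`,
#'   `donor_fraction`.
#' @export
individual_chromosome_fraction <- function(dosages, chroms = NULL) {
  got <- dosages %>%
    group_by(sample_id, chrom) %>%
    summarise(n_sites = n(), donor_fraction = mean(dosage) / 2,
              .groups = "drop")
  if (is.null(chroms)) return(got)
  tidyr::expand_grid(sample_id = unique(dosages$sample_id),
                     chrom = chroms) %>%
    left_join(got, by = c("sample_id", "chrom")) %>%
    mutate(n_sites = ifelse(is.na(n_sites), 0L, n_sites))
}

# one-sided (x > y) Mann-Whitney by exhaustive enumeration of all
# assignments of the observed values, conditioning on ties
exact_mw_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  r <- rank(v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- combn(length(v), n1)
  u_perm <- apply(picks, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  if (all(u_perm == u_perm[1])) return(0.5)  # degenerate: all values tied
  mean(u_perm >= u_obs)
}

#' Rank-based enrichment test for donor ancestry in selected windows
#'
#' Two-sample Mann-Whitney/Wilcoxon rank-sum test, one-sided by default
#' (selected > control).  For group sizes of at most 8 the p-value is an
#' exact enumeration over all assignments of the observed values
#' (conditioning on ties); otherwise the normal approximation with tie and
#' continuity corrections is used.  A fully tied comparison carries no
#' evidence and returns p = 0.5.
#'
#' @param fractions Numeric vector of per-window donor fractions (NA
#'   dropped), or a data frame holding `donor_fraction`.
#' @param selected Logical mask, TRUE for selected windows.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exact_max Largest group size for the exact route (default 8).
#' @return A `wilcoxon_enrichment` object (see [tidy()]/[glance()]
#'   methods) with the U statistic, z, p-value and group means.
#' @export
enrichment_wilcoxon <- function(fractions, selected,
                                alternative = c("greater", "two.sided"),
                                exact_max = 8L) {
  alternative <- match.arg(alternative)
  if (is.data.frame(fractions)) fractions <- fractions$donor_fraction
  stopifnot(length(fractions) == length(selected))
  ok <- !is.na(fractions) & !is.na(selected)
  x <- fractions[ok & selected]   # selected group
  y <- fractions[ok & !selected]  # control group
  if (length(x) == 0 || length(y) == 0) {
    abort("both the selected and the control group must be non-empty")
  }
  n1 <- length(x); n2 <- length(y); nn <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  mu <- n1 * n2 / 2
  z <- if (sigma2 > 0) (u - mu - 0.5) / sqrt(sigma2) else 0

  method <- "normal approximation"
  if (n1 <= exact_max && n2 <= exact_max) {
    method <- "exact enumeration"
    p_greater <- exact_mw_p(x, y)
  } else if (sigma2 == 0) {
    p_greater <- 0.5
  } else {
    p_greater <- pnorm(z, lower.tail = FALSE)
  }
  p <- if (alternative == "greater") p_greater else min(1, 2 * min(
    p_greater, 1 - p_greater
  ))
  structure(
    list(statistic = u, z = z, p.value = p, alternative = alternative,
         method = method, n_selected = n1, n_control = n2,
         mean_selected = mean(x), mean_control = mean(y),
         values_selected = x, values_control = y),
    class = "wilcoxon_enrichment"
  )
}

#' @export
print.wilcoxon_enrichment <- function(x, ...) {
  cat("Wilcoxon rank-sum enrichment test (", x$method, ")\n", sep = "")
  cat(sprintf("  U = %.1f, z = %.3f, p (%s) = %.4g\n",
              x$statistic, x$z, x$alternative, x$p.value))
  cat(sprintf("  mean donor fraction: selected %.4g (n=%d) vs control %.4g (n=%d)\n",
              x$mean_selected, x$n_selected, x$mean_control, x$n_control))
  invisible(x)
}

#' Correlation between window differentiation and donor ancestry
#'
#' Pearson correlation across windows between F_ST and the donor-ancestry
#' fraction; NA pairs are dropped and NA is returned for fewer than 3
#' complete pairs or constant inputs.
#'
#' @param window_fst Numeric vector of per-window F_ST values.
#' @param window_fractions Numeric vector of per-window donor fractions.
#' @return Pearson r (or NA).
#' @export
fst_ancestry_correlation <- function(window_fst, window_fractions) {
  stopifnot(length(window_fst) == length(window_fractions))
  ok <- !is.na(window_fst) & !is.na(window_fractions)
  if (sum(ok) < 3L) return(NA_real_)
  if (sd(window_fst[ok]) == 0 || sd(window_fractions[ok]) == 0) {
    return(NA_real_)
  }
  cor(window_fst[ok], window_fractions[ok])
}
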