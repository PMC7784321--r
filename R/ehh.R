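new_ehh_curve <- function(data, statistic, core_site, core_pos, allele,
                          cutoff, left_censored, right_censored,
                          reason = NA_character_) {
  structure(
    data,
    statistic = statistic, core_site = core_site, core_pos = core_pos,
    allele = allele, cutoff = cutoff,
    truncation = c(
      left = if (left_censored) "chromosome_edge" else "cutoff_reached",
      right = if (right_censored) "chromosome_edge" else "cutoff_reached"
    ),
    reason = reason,
    class = c("ehh_curve", class(data))
  )
}

decay_to_tibble <- function(dec, panel) {
  left <- tibble(side = "left", site = rev(dec$left$idx),
                 pos = panel$positions[rev(dec$left$idx)],
                 value = rev(dec$left$value))
  right <- tibble(side = "right", site = dec$right$idx[-1],
                  pos = panel$positions[dec$right$idx[-1]],
                  value = dec$right$value[-1])
  bind_rows(left, right)
}

assert_one_chrom <- function(panel) {
  if (length(unique(panel$chrom)) != 1L) {
    abort("EHH statistics are per-chromosome; subset the panel first")
  }
  invisible(panel)
}

#' Allele-specific extended haplotype homozygosity (EHH) curve
#'
#' For the carriers of `allele` at the core site, EHH over the inclusive
#' marker span from the core to marker `t` is the unbiased probability that
#' two random carrier haplotypes are identical over the span:
#' `sum_k n_k (n_k - 1) / (n_c (n_c - 1))` over distinct carrier haplotype
#' strings.  The curve starts at 1 and is non-increasing; it is truncated
#' at the last marker with value `>= cutoff` or at the chromosome edge.
#'
#' @param panel A complete (no missing entries) single-population,
#'   single-chromosome [haplotype_panel()].
#' @param core Site index of the core SNP.
#' @param allele Core allele, 0 (ref) or 1 (alt).
#' @param cutoff Truncation cutoff (default 0.05).
#' @return An `ehh_curve` tibble with columns `side`, `site`, `pos`,
#'   `value`, ordered by position; attributes record the core, the
#'   truncation reason per side, and (for degenerate cores) an NA reason.
#' @export
ehh_curve <- function(panel, core, allele, cutoff = 0.05) {
  assert_complete(panel, "ehh_curve()")
  assert_one_chrom(panel)
  rows <- which(panel$hap[, core] == allele)
  if (length(rows) < 2L) {
    return(new_ehh_curve(
      tibble(side = character(), site = integer(), pos = integer(),
             value = numeric()),
      "EHH", core, panel$positions[core], allele, cutoff, FALSE, FALSE,
      reason = "fewer than 2 carrier haplotypes"
    ))
  }
  dec <- cpp_decay(panel$hap, rows, core, FALSE, cutoff)
  new_ehh_curve(decay_to_tibble(dec, panel), "EHH", core,
                panel$positions[core], allele, cutoff,
                dec$left$censored, dec$right$censored)
}

#' Site-specific EHH (EHHS) curve
#'
#' Pools both core alleles: `EHHS(core..t) = H(core..t) / H(core)` where
#' `H(span) = sum_k n_k (n_k - 1) / (n (n - 1))` is the unbiased haplotype
#' homozygosity over all haplotypes of the population.  Starts at 1,
#' non-increasing, truncated as in [ehh_curve()].
#'
#' @inheritParams ehh_curve
#' @return An `ehh_curve` tibble (statistic `"EHHS"`).
#' @export
ehhs_curve <- function(panel, core, cutoff = 0.05) {
  assert_complete(panel, "ehhs_curve()")
  assert_one_chrom(panel)
  if (nrow(panel$hap) < 2L) {
    return(new_ehh_curve(
      tibble(side = character(), site = integer(), pos = integer(),
             value = numeric()),
      "EHHS", core, panel$positions[core], NA_integer_, cutoff, FALSE, FALSE,
      reason = "fewer than 2 haplotypes"
    ))
  }
  dec <- cpp_decay(panel$hap, seq_len(nrow(panel$hap)), core, TRUE, cutoff)
  new_ehh_curve(decay_to_tibble(dec, panel), "EHHS", core,
                panel$positions[core], NA_integer_, cutoff,
                dec$left$censored, dec$right$censored)
}

#' Integrate an EHH/EHHS decay curve (iHH / iES)
#'
#' Trapezoid rule over physical positions, summing the left and right
#' sides; only markers with value `>= cutoff` enter (the stored curve
#' already honours this).  If the curve never fell below the cutoff before
#' the chromosome edge on either side, the integral is edge-censored and
#' NA is returned rather than a biased partial area.
#'
#' @param curve An `ehh_curve` from [ehh_curve()] or [ehhs_curve()].
#' @return The bp-scaled area (iHH for EHH curves, iES for EHHS curves),
#'   or NA.
#' @export
integrate_curve <- function(curve) {
  if (!is.na(attr(curve, "reason"))) return(NA_real_)
  if (any(attr(curve, "truncation") == "chromosome_edge")) return(NA_real_)
  core_pos <- attr(curve, "core_pos")
  cutoff <- attr(curve, "cutoff")
  area_side <- function(s) {
    d <- curve[curve$side == s & curve$value >= cutoff, ]
    pts <- tibble(pos = c(core_pos, d$pos), value = c(1, d$value)) %>%
      arrange(abs(pos - core_pos))
    if (nrow(pts) < 2L) return(0)
    sum(0.5 * (pts$value[-1] + pts$value[-nrow(pts)]) * abs(diff(pts$pos)))
  }
  area_side("left") + area_side("right")
}

# iES at every site of a (possibly multi-chromosome) complete panel
ies_vector <- function(panel, cutoff = 0.05) {
  assert_complete(panel, "iES scan")
  out <- numeric(n_sites(panel))
  for (cc in unique(panel$chrom)) {
    idx <- which(panel$chrom == cc)
    out[idx] <- cpp_ies_scan(panel$hap[, idx, drop = FALSE],
                             as.numeric(panel$positions[idx]), cutoff)
  }
  out
}

#' Per-site iES scan
#'
#' @inheritParams ehh_curve
#' @param panel A complete [haplotype_panel()] (one population).
#' @return A tibble with columns `chrom`, `pos`, `ies` (NA where the decay
#'   is edge-censored or fewer than 2 haplotypes are pairable).
#' @export
ies_scan <- function(panel, cutoff = 0.05) {
  tibble(chrom = panel$chrom, pos = panel$positions,
         ies = ies_vector(panel, cutoff))
}

standardize_in_bins <- function(x, freq, bin_width, min_bin_snps, center) {
  bin <- pmin(floor(freq / bin_width), floor(1 / bin_width) - 1L)
  lev <- sort(unique(bin[!is.na(x)]))
  # merge sparse bins with their right neighbour (left for the last bin)
  repeat {
    counts <- vapply(lev, function(b) sum(bin == b & !is.na(x)), integer(1))
    small <- which(counts < min_bin_snps)
    if (!length(small) || length(lev) == 1L) break
    j <- small[1]
    tgt <- if (j < length(lev)) lev[j + 1] else lev[j - 1]
    bin[bin == lev[j]] <- tgt
    lev <- lev[-j]
  }
  out <- rep(NA_real_, length(x))
  for (b in lev) {
    sel <- bin == b & !is.na(x)
    mu <- if (center == "median") median(x[sel]) else mean(x[sel])
    s <- sd(x[sel])
    if (!is.na(s) && s > 0) out[sel] <- (x[sel] - mu) / s
  }
  out
}

#' Within-population iHS scan
#'
#' Per SNP, the unstandardized score is `ln(iHH_ancestral / iHH_derived)`;
#' scores are standardized to mean 0, SD 1 within derived-allele-frequency
#' bins (default width 0.05; bins with fewer than `min_bin_snps` SNPs are
#' merged with a neighbour).  Strongly negative iHS marks unusually long
#' haplotypes around the derived allele.
#'
#' @param panel A complete single-population [haplotype_panel()].
#' @param ancestral Per-site ancestral allele (0/1); default 0, i.e. REF.
#' @param cutoff EHH truncation cutoff.
#' @param min_carriers Minimum carriers per allele (default 2).
#' @param bin_width Derived-frequency bin width for standardization.
#' @param min_bin_snps Minimum SNPs per bin before merging.
#' @return A tibble with columns `chrom`, `pos`, `freq_derived`, `ihh_anc`,
#'   `ihh_der`, `ihs_raw`, `ihs`, `note`.
#' @export
ihs_scan <- function(panel, ancestral = NULL, cutoff = 0.05,
                     min_carriers = 2L, bin_width = 0.05,
                     min_bin_snps = 10L) {
  assert_complete(panel, "ihs_scan()")
  anc <- ancestral %||% rep(0L, n_sites(panel))
  stopifnot(length(anc) == n_sites(panel), all(anc %in% 0:1))
  ihh <- matrix(NA_real_, n_sites(panel), 2L)
  for (cc in unique(panel$chrom)) {
    idx <- which(panel$chrom == cc)
    ihh[idx, ] <- cpp_ihh_scan(panel$hap[, idx, drop = FALSE],
                               as.numeric(panel$positions[idx]),
                               as.integer(anc[idx]), cutoff,
                               as.integer(min_carriers))
  }
  p_alt <- site_freq(panel)
  freq_der <- ifelse(anc == 0L, p_alt, 1 - p_alt)
  raw <- ifelse(ihh[, 1] > 0 & ihh[, 2] > 0, log(ihh[, 1] / ihh[, 2]),
                NA_real_)
  raw[freq_der <= 0 | freq_der >= 1] <- NA_real_
  ihs <- standardize_in_bins(raw, freq_der, bin_width, min_bin_snps, "mean")
  tibble(
    chrom = panel$chrom, pos = panel$positions, freq_derived = freq_der,
    ihh_anc = ihh[, 1], ihh_der = ihh[, 2], ihs_raw = raw, ihs = ihs,
    note = ifelse(is.na(raw), "undefined_ihh", NA_character_)
  )
}

assert_same_sites <- function(a, b) {
  same <- a$chrom == b$chrom & a$positions == b$positions &
    a$ref == b$ref & a$alt == b$alt
  if (n_sites(a) != n_sites(b)) {
    abort(sprintf("site sets differ: %d vs %d sites",
                  n_sites(a), n_sites(b)))
  }
  if (!all(same)) {
    j <- which(!same)[1]
    abort(sprintf(
      "site sets differ, first discrepancy at index %d (%s:%d vs %s:%d)",
      j, a$chrom[j], a$positions[j], b$chrom[j], b$positions[j]
    ))
  }
  invisible(TRUE)
}

#' Cross-population Rsb scan
#'
#' Per SNP, `lnR = ln(iES_focal / iES_ref)`; the standardized score
#' `Rsb = (lnR - median(lnR)) / SD(lnR)` (median-centred by default, robust
#' to the sweep tail).  Positive Rsb means longer haplotype homozygosity in
#' the focal population, the signature of a sweep specific to it.  Sites
#' with undefined iES in either population are NA.
#'
#' @param panel_focal,panel_ref Complete [haplotype_panel()]s on the same
#'   site set (one population each).
#' @param cutoff EHHS truncation cutoff (default 0.05).
#' @param center `"median"` (default) or `"mean"` centring for
#'   standardization.
#' @return A tibble with columns `chrom`, `pos`, `ies_focal`, `ies_ref`,
#'   `lnr`, `rsb`, `note`.
#' @export
rsb_scan <- function(panel_focal, panel_ref, cutoff = 0.05,
                     center = c("median", "mean")) {
  center <- match.arg(center)
  assert_same_sites(panel_focal, panel_ref)
  ies_f <- ies_vector(panel_focal, cutoff)
  ies_r <- ies_vector(panel_ref, cutoff)
  rsb_from_ies(panel_focal, ies_f, ies_r, center)
}

rsb_from_ies <- function(panel, ies_f, ies_r, center = "median") {
  # log difference (not log of the ratio) so lnR(A,B) = -lnR(B,A) holds
  # bit-exactly under argument swap
  lnr <- ifelse(!is.na(ies_f) & !is.na(ies_r) & ies_f > 0 & ies_r > 0,
                log(ies_f) - log(ies_r), NA_real_)
  mu <- if (center == "median") median(lnr, na.rm = TRUE)
        else mean(lnr, na.rm = TRUE)
  s <- sd(lnr, na.rm = TRUE)
  rsb <- if (is.na(s) || s == 0) rep(NA_real_, length(lnr)) else (lnr - mu) / s
  tibble(
    chrom = panel$chrom, pos = panel$positions,
    ies_focal = ies_f, ies_ref = ies_r, lnr = lnr, rsb = rsb,
    note = ifelse(is.na(lnr), "undefined_ies", NA_character_)
  )
}
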