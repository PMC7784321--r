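# small constructors and independent oracles shared across the suite

# panel from a haplotype matrix; positions default to 1 kb spacing
mk_panel <- function(hap, positions = NULL, chrom = "chr1", pops = NULL,
                     ref = NULL, alt = NULL) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  n_site <- ncol(hap)
  n_samp <- nrow(hap) / 2L
  positions <- positions %||% as.integer(seq_len(n_site) * 1000L)
  mk <- function(x, d) if (is.null(x)) rep(d, n_site) else x
  haplotype_panel(
    chrom = rep(chrom, n_site), positions = positions,
    ref = mk(ref, "A"), alt = mk(alt, "C"), hap = hap,
    sample_ids = paste0("s", seq_len(n_samp)),
    populations = pops %||% rep("pop1", n_samp)
  )
}

# split one panel's samples into two single-population panels
split_panel <- function(panel, n_a, labels = c("A", "B")) {
  ids <- panel$sample_ids
  mk <- function(keep, lab) {
    rows <- tropiscan:::hap_rows_of(panel, keep)
    haplotype_panel(panel$chrom, panel$positions, panel$ref, panel$alt,
                    panel$hap[rows, , drop = FALSE], keep,
                    rep(lab, length(keep)))
  }
  list(mk(ids[seq_len(n_a)], labels[1]),
       mk(ids[(n_a + 1):length(ids)], labels[2]))
}

# diploid genotype sampling from per-population allele frequencies
panel_from_freqs <- function(freq, n_dip, positions = NULL,
                             chrom = "chr1") {
  pops <- colnames(freq)
  hap <- do.call(rbind, lapply(pops, function(pp) {
    n_hap <- 2L * n_dip[[pp]]
    matrix(rbinom(n_hap * nrow(freq), 1L, rep(freq[, pp], each = n_hap)),
           nrow = n_hap)
  }))
  n_site <- nrow(freq)
  haplotype_panel(
    chrom = rep(chrom, n_site),
    positions = positions %||% as.integer(seq_len(n_site) * 100L),
    ref = rep("A", n_site), alt = rep("C", n_site), hap = hap,
    sample_ids = paste0("s", seq_len(sum(n_dip))),
    populations = rep(pops, times = n_dip)
  )
}

# brute-force EHH oracle: materialize carrier substrings over the
# inclusive span and count identical pairs
brute_ehh <- function(hap, core, allele, t) {
  carriers <- which(hap[, core] == allele)
  n <- length(carriers)
  if (n < 2) return(NA_real_)
  span <- min(core, t):max(core, t)
  strs <- apply(hap[carriers, span, drop = FALSE], 1, paste, collapse = "")
  cnt <- table(strs)
  sum(cnt * (cnt - 1)) / (n * (n - 1))
}

# brute-force EHHS oracle: unbiased haplotype homozygosity of the span,
# normalized by the core-site homozygosity.  The 1/(n(n-1)) factors cancel,
# so the ratio of integer pair counts is taken in one division (exact
# comparability with any correct implementation).
brute_ehhs <- function(hap, core, t) {
  pair_sum <- function(span) {
    strs <- apply(hap[, span, drop = FALSE], 1, paste, collapse = "")
    cnt <- table(strs)
    sum(cnt * (cnt - 1))
  }
  span <- min(core, t):max(core, t)
  pair_sum(span) / pair_sum(core:core)
}

random_complete_panel <- function(seed, max_hap = 20, max_sites = 50) {
  withr::with_seed(seed, {
    n_hap <- 2L * sample(2:(max_hap / 2), 1)
    n_site <- sample(3:max_sites, 1)
    freq <- runif(n_site, 0.1, 0.9)
    hap <- matrix(rbinom(n_hap * n_site, 1L, rep(freq, each = n_hap)),
                  nrow = n_hap)
  })
  mk_panel(hap)
}
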