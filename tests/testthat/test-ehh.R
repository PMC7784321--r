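test_that("allele-specific EHH matches the pair-counting definition", {
  # 4 carriers identical over the span -> 1
  same <- mk_panel(rbind(c(1L, 0L), c(1L, 0L), c(1L, 0L), c(1L, 0L),
                         c(0L, 1L), c(0L, 1L)))
  cv <- ehh_curve(same, core = 1, allele = 1)
  expect_equal(cv$value[cv$site == 2], 1)

  # carriers split 2/2 -> (2 + 2) / 12 = 1/3
  split22 <- mk_panel(rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L)))
  cv2 <- ehh_curve(split22, core = 1, allele = 1)
  expect_equal(cv2$value[cv2$site == 2], 1 / 3)

  # all carriers distinct -> 0 (below cutoff, so truncated before site 2)
  distinct <- mk_panel(rbind(c(1L, 0L, 0L), c(1L, 1L, 0L),
                             c(0L, 0L, 0L), c(0L, 1L, 1L)))
  cv3 <- ehh_curve(distinct, core = 1, allele = 1)
  expect_false(2 %in% cv3$site)
  expect_equal(brute_ehh(distinct$hap, 1, 1L, 2), 0)

  # fewer than 2 carriers -> degenerate curve with a reason
  mono <- mk_panel(rbind(c(1L, 0L), c(0L, 0L), c(0L, 0L), c(0L, 0L)))
  cv4 <- ehh_curve(mono, core = 1, allele = 1)
  expect_match(attr(cv4, "reason"), "carrier")
  expect_true(is.na(integrate_curve(cv4)))
})

test_that("EHHS matches the normalized haplotype-homozygosity definition", {
  # core split 3/3 (H = 12/30); extension refines to {3,2,1} (H = 8/30)
  hap <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 0L),
               c(1L, 0L), c(1L, 0L), c(1L, 1L))
  p <- mk_panel(hap)
  cv <- ehhs_curve(p, core = 1)
  expect_equal(cv$value[cv$site == 2], (8 / 30) / (12 / 30))
  expect_equal(brute_ehhs(hap, 1, 2), 2 / 3)

  # extension that keeps every haplotype in its core class -> stays 1
  keep <- mk_panel(rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L),
                         c(1L, 1L), c(1L, 1L)))
  cvk <- ehhs_curve(keep, core = 1)
  expect_equal(cvk$value[cvk$site == 2], 1)

  # all haplotypes distinct at the extension -> 0, truncated
  dist <- mk_panel(rbind(c(0L, 0L, 0L), c(0L, 1L, 0L), c(1L, 0L, 0L),
                         c(1L, 1L, 1L)))
  cvd <- ehhs_curve(dist, core = 1)
  expect_false(2 %in% cvd$site)
})

test_that("curves agree with the brute-force oracle and are monotone in [0,1]", {
  for (seed in 1:25) {
    p <- random_complete_panel(seed, max_hap = 16, max_sites = 30)
    core <- withr::with_seed(seed + 1000, sample(n_sites(p), 1))
    cv <- ehhs_curve(p, core, cutoff = 0)
    for (s in c("left", "right")) {
      d <- cv[cv$side == s, ]
      if (nrow(d) > 1) expect_true(all(diff(d$value) * (if (s == "left") -1 else 1) <= 1e-12))
      for (k in seq_len(nrow(d))) {
        expect_equal(d$value[k], brute_ehhs(p$hap, core, d$site[k]))
      }
    }
    expect_true(all(cv$value >= 0 & cv$value <= 1))
  }
})

test_that("curve integration follows the trapezoid-above-cutoff rule", {
  # hand-built decay: (core, 1), (+1000, 0.5), (+2000, 0.04); the 0.04
  # marker is below the cutoff and excluded -> area (1 + 0.5)/2 * 1000
  curve <- tropiscan:::new_ehh_curve(
    tibble::tibble(side = c("right", "right"), site = c(2L, 3L),
                   pos = c(2000L, 3000L), value = c(0.5, 0.04)),
    "EHHS", 1L, 1000L, NA_integer_, 0.05, FALSE, FALSE
  )
  expect_equal(integrate_curve(curve), 750)

  # 1 at the core only, sub-cutoff flanks -> area 0, not NA
  spike <- mk_panel(rbind(c(0L, 0L, 0L), c(0L, 1L, 0L), c(1L, 0L, 1L),
                          c(1L, 1L, 1L)))
  cv <- ehhs_curve(spike, core = 2)
  expect_equal(integrate_curve(cv), 0)

  # curve that never falls below cutoff before the edge -> edge-censored NA
  flat <- mk_panel(matrix(rep(c(0L, 0L, 1L, 1L), 3), nrow = 4))
  expect_true(is.na(integrate_curve(ehhs_curve(flat, core = 2))))

  # curve-route integration equals the compiled iES scan
  for (seed in 26:31) {
    p <- random_complete_panel(seed, max_hap = 14, max_sites = 40)
    ies <- ies_scan(p)$ies
    for (core in unique(round(seq(1, n_sites(p), length.out = 4)))) {
      expect_equal(integrate_curve(ehhs_curve(p, core)), ies[core])
    }
  }
})

test_that("iES is positive wherever defined", {
  p <- random_complete_panel(41, max_hap = 18, max_sites = 50)
  ies <- ies_scan(p)$ies
  expect_true(all(ies[!is.na(ies)] > 0))
})

test_that("iHS is zero for symmetric allele classes and standardizes within bins", {
  # two identical ref carriers and two identical alt carriers with
  # mirror-image flanking structure -> identical iHH for both alleles
  hap <- cbind(
    c(0L, 1L, 0L, 1L),                      # both classes split here
    c(0L, 0L, 1L, 1L),                      # no refinement
    c(0L, 0L, 1L, 1L),                      # core: 2 ancestral, 2 derived
    c(0L, 0L, 1L, 1L),                      # no refinement
    c(0L, 1L, 0L, 1L)                       # both classes split here
  )
  p <- mk_panel(hap)
  sc <- ihs_scan(p, min_bin_snps = 1)
  expect_equal(sc$ihs_raw[3], 0)

  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), pop_sizes = c(focal = 15),
                    seed = 5)
  sp <- simulate_panel(cfg)
  sc2 <- ihs_scan(sp)
  ok <- !is.na(sc2$ihs)
  expect_gt(mean(ok), 0.5)
  expect_lt(abs(mean(sc2$ihs[ok])), 0.15)
  expect_lt(abs(sd(sc2$ihs[ok]) - 1), 0.15)
})

test_that("an implanted sweep skews iHS and elevates its magnitude locally", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 3e6), pop_sizes = c(focal = 15),
                    seed = 9)
  p <- simulate_panel(cfg)
  swept <- implant_sweep(p, pop = "focal", chrom = "chr1", locus = 1.5e6,
                         beta = 0.9, tract_bp = 4e5, seed = 10)
  sc <- ihs_scan(swept)
  near <- abs(sc$pos - 1.5e6) < 2e5
  ok <- !is.na(sc$ihs)
  expect_gt(mean(abs(sc$ihs[near & ok])), mean(abs(sc$ihs[!near & ok])))
  # where the favored haplotype carries mostly derived alleles, iHS < 0
  f <- site_freq(swept)
  derived_swept <- near & ok & f > 0.7 & f < 1
  if (sum(derived_swept) >= 3) expect_lt(mean(sc$ihs[derived_swept]), 0)
})

test_that("Rsb is zero against itself, anti-symmetric under swap, and strict about sites", {
  p <- random_complete_panel(51, max_hap = 16, max_sites = 40)
  sc_same <- rsb_scan(p, p)
  expect_true(all(abs(sc_same$lnr[!is.na(sc_same$lnr)]) < 1e-12))

  q <- random_complete_panel(52, max_hap = 16, max_sites = 40)
  q <- subset_sites(q, seq_len(min(n_sites(p), n_sites(q))))
  p2 <- subset_sites(p, seq_len(n_sites(q)))
  ab <- rsb_scan(p2, q)
  ba <- rsb_scan(q, p2)
  expect_equal(ab$lnr, -ba$lnr)
  expect_equal(ab$rsb, -ba$rsb)

  shifted <- p2
  shifted$positions[2] <- shifted$positions[2] + 1L
  expect_error(rsb_scan(p2, shifted), "discrepancy")
})

test_that("under panmixia extreme |Rsb| occurs at roughly the Gaussian-tail rate", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), site_density = 5e-4,
                    pop_sizes = c(pool = 24), seed = 61)
  pool <- simulate_panel(cfg)
  sp <- split_panel(pool, 12)
  sc <- rsb_scan(sp[[1]], sp[[2]])
  rate <- mean(abs(sc$rsb) > 3, na.rm = TRUE)
  expect_lt(rate, 0.02)
})
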