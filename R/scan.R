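# grid window index containing each (chrom, pos), NA when outside the grid
window_of_pos <- function(chrom, pos, grid) {
  out <- rep(NA_integer_, length(pos))
  for (cc in unique(chrom)) {
    g <- which(grid$chrom == cc)
    if (!length(g)) next
    s <- which(chrom == cc)
    j <- findInterval(pos[s], grid$start[g])
    ok <- j >= 1L & pos[s] <= grid$end[g][pmax(j, 1L)]
    out[s[ok]] <- g[j[ok]]
  }
  out
}

#' Permutation p-values for an Rsb scan
#'
#' The null is built by randomly reassigning *individuals* (keeping both
#' haplotypes of an individual together, so within-individual phase
#' structure is preserved) to two groups of the original sizes, and
#' recomputing the Rsb scan genome-wide for each permutation.  The per-SNP
#' permutation p-value is the fraction of permutations in which the
#' permuted Rsb at that SNP is `>=` the observed one, which corrects for
#' locally inflated disequilibrium.  Deterministic given `seed`.
#'
#' @param panel_focal,panel_ref Complete [haplotype_panel()]s on the same
#'   site set.
#' @param observed Optional precomputed observed scan from [rsb_scan()]
#'   (recomputed when NULL).
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed (required).
#' @param cutoff,center Passed to the Rsb computation.
#' @param comparison `"per_snp"` (default) compares each SNP against its
#'   own permuted values; `"pooled"` compares against the pooled permuted
#'   distribution across all SNPs.
#' @param statistic Which per-SNP statistic to compare: `"lnr"` (default),
#'   the raw log iES ratio, or `"rsb"`, the scan-standardized score.  Both
#'   are exchangeable under label permutation and give a calibrated null;
#'   the raw ratio is the default because standardization constants differ
#'   between the observed and each permuted scan (real sweeps inflate the
#'   observed scan's SD), which makes cross-scan comparison of the
#'   standardized score conservative exactly at strong signals.
#' @param pseudocount If TRUE, p = (count + 1) / (n_perm + 1) so p is never
#'   exactly 0.
#' @param keep_perms If TRUE the per-permutation statistic matrix (SNPs x
#'   permutations) is attached as attribute `"perm_stats"`, e.g. for
#'   leave-one-out null-calibration checks.
#' @return The observed scan tibble with an added `perm_p` column.
#' @export
permute_rsb_pvalues <- function(panel_focal, panel_ref, observed = NULL,
                                n_perm = 100, seed, cutoff = 0.05,
                                center = "median",
                                comparison = c("per_snp", "pooled"),
                                statistic = c("lnr", "rsb"),
                                pseudocount = FALSE, keep_perms = FALSE) {
  comparison <- match.arg(comparison)
  statistic <- match.arg(statistic)
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (n_samples(panel_focal) < 2L || n_samples(panel_ref) < 2L) {
    abort("each population needs at least 2 individuals")
  }
  assert_same_sites(panel_focal, panel_ref)
  assert_complete(panel_focal, "permute_rsb_pvalues()")
  assert_complete(panel_ref, "permute_rsb_pvalues()")
  observed <- observed %||% rsb_scan(panel_focal, panel_ref, cutoff, center)

  hap_all <- rbind(panel_focal$hap, panel_ref$hap)
  n_a <- n_samples(panel_focal)
  n_tot <- n_a + n_samples(panel_ref)
  chrom_idx <- split(seq_len(n_sites(panel_focal)), panel_focal$chrom)
  pos <- as.numeric(panel_focal$positions)

  ies_of <- function(ind) {
    rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    out <- numeric(length(pos))
    for (idx in chrom_idx) {
      out[idx] <- cpp_ies_scan(hap_all[rows, idx, drop = FALSE], pos[idx],
                               cutoff)
    }
    out
  }

  obs <- observed[[statistic]]
  count <- numeric(length(obs))
  n_pool <- 0
  perm_stats <- if (keep_perms) {
    matrix(NA_real_, nrow = length(obs), ncol = n_perm)
  }
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      shuffled <- sample.int(n_tot)
      ies_f <- ies_of(shuffled[seq_len(n_a)])
      ies_r <- ies_of(shuffled[(n_a + 1L):n_tot])
      perm <- rsb_from_ies(panel_focal, ies_f, ies_r, center)[[statistic]]
      if (keep_perms) perm_stats[, b] <- perm
      if (comparison == "per_snp") {
        count <- count + (!is.na(perm) & !is.na(obs) & perm >= obs)
      } else {
        sv <- sort(perm[!is.na(perm)])
        n_pool <- n_pool + length(sv)
        # permuted values >= obs, per SNP, against the pooled null
        count <- count + (length(sv) - findInterval(obs, sv,
                                                    left.open = TRUE))
      }
    }
  })
  denom <- if (comparison == "per_snp") n_perm else n_pool
  p <- if (pseudocount) (count + 1) / (denom + 1) else count / denom
  p[is.na(obs)] <- NA_real_
  out <- observed %>% mutate(perm_p = p)
  if (keep_perms) attr(out, "perm_stats") <- perm_stats
  out
}

#' Select candidate selection windows from an Rsb scan
#'
#' Each window of the grid is scored by its maximum-Rsb SNP.  Windows with
#' a positive score are ranked by that score and the `top_n` best are taken
#' (ties at the boundary expand the cut; partial end-of-chromosome windows
#' are excluded from the ranking).  Of those, windows whose scoring SNP has
#' permutation p-value `< alpha` are retained.
#'
#' @param scan An Rsb scan tibble with `perm_p` (from
#'   [permute_rsb_pvalues()]).
#' @param grid Window grid from [make_windows()] / [make_window_grid()].
#' @param top_n Number of top windows considered (default 2000).
#' @param alpha Permutation p-value threshold (default 0.05).
#' @return A `candidate_windows` object: a tibble with one row per scored
#'   window (`chrom`, `start`, `end`, `partial`, `n_snps`, `max_rsb`,
#'   `scoring_pos`, `perm_p`, `in_top`, `retained`,
#'   `excluded_by_control`).
#' @export
select_candidate_windows <- function(scan, grid, top_n = 2000,
                                     alpha = 0.05) {
  stopifnot(all(c("rsb", "perm_p") %in% names(scan)))
  w <- window_of_pos(scan$chrom, scan$pos, grid)
  scored <- scan %>%
    mutate(window = w) %>%
    filter(!is.na(window), !is.na(rsb)) %>%
    group_by(window) %>%
    summarise(
      n_snps = n(),
      scoring_pos = pos[which.max(rsb)],
      max_rsb = max(rsb),
      perm_p = perm_p[which.max(rsb)],
      .groups = "drop"
    )
  out <- grid %>%
    mutate(window = row_number()) %>%
    inner_join(scored, by = "window") %>%
    select(-window)

  eligible <- out$max_rsb > 0 & !out$partial
  n_pos <- sum(eligible)
  if (n_pos < top_n) {
    inform(sprintf(
      "only %d window(s) with positive Rsb; all considered (top_n = %d)",
      n_pos, top_n
    ))
  }
  in_top <- rep(FALSE, nrow(out))
  if (n_pos > 0) {
    sc <- out$max_rsb[eligible]
    thr <- if (n_pos <= top_n) min(sc) else sort(sc, decreasing = TRUE)[top_n]
    in_top[eligible] <- sc >= thr   # ties at the boundary expand the cut
  }
  out <- out %>%
    mutate(
      in_top = in_top,
      excluded_by_control = FALSE,
      retained = in_top & perm_p < alpha
    )
  structure(out, top_n = top_n, alpha = alpha,
            class = c("candidate_windows", class(out)))
}

#' Exclude candidate intervals shared with a control comparison
#'
#' Candidate windows overlapping (by at least 1 bp, same chromosome) any
#' *retained* window of the control-pair scan are flagged
#' `excluded_by_control` and dropped from the retained set; what remains is
#' the final population-exclusive candidate set.
#'
#' @param candidates,control_candidates `candidate_windows` objects on the
#'   same genome coordinates.
#' @return `candidates` with updated `excluded_by_control` and `retained`
#'   flags.
#' @export
exclude_control_intervals <- function(candidates, control_candidates) {
  ctrl <- control_candidates %>% filter(retained)
  if (nrow(ctrl) == 0) return(candidates)
  hit <- vapply(seq_len(nrow(candidates)), function(i) {
    any(ctrl$chrom == candidates$chrom[i] &
          ctrl$start <= candidates$end[i] &
          ctrl$end >= candidates$start[i])
  }, logical(1))
  candidates %>%
    mutate(
      excluded_by_control = hit,
      retained = retained & !hit
    )
}

#' Merge retained candidate windows into reporting intervals
#'
#' Adjacent (sharing a boundary) or overlapping retained windows are merged
#' into maximal intervals; each merged interval carries its best (maximum)
#' Rsb and smallest permutation p-value.
#'
#' @param candidates A `candidate_windows` object.
#' @return A tibble with columns `chrom`, `start`, `end`, `n_windows`,
#'   `max_rsb`, `min_p`.
#' @export
merge_intervals <- function(candidates) {
  kept <- candidates %>% filter(retained) %>% arrange(chrom, start)
  if (nrow(kept) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), max_rsb = numeric(),
                  min_p = numeric()))
  }
  kept %>%
    group_by(chrom) %>%
    mutate(gap = start > lag(end, default = first(start)) + 1L,
           run = cumsum(gap)) %>%
    group_by(chrom, run) %>%
    summarise(
      start = min(start), end = max(end), n_windows = n(),
      max_rsb = max(max_rsb), min_p = min(perm_p), .groups = "drop"
    ) %>%
    select(chrom, start, end, n_windows, max_rsb, min_p) %>%
    arrange(chrom, start)
}

#' Export intervals as BED (0-based half-open)
#'
#' @param intervals A tibble with `chrom`, `start`, `end` (1-based
#'   inclusive internal coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  bed <- tibble(chrom = intervals$chrom,
                start = intervals$start - 1L,  # to 0-based half-open
                end = intervals$end)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
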