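BASES <- c("A", "C", "G", "T")

new_pwm <- function(id, name, probs, background) {
  stopifnot(nrow(probs) == 4L, ncol(probs) >= 1L)
  rownames(probs) <- BASES
  structure(list(id = id, name = name, probs = probs,
                 background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), width %d\n", x$id, x$name, ncol(x$probs)))
  invisible(x)
}

#' Read a JASPAR pfm motif collection
#'
#' Parses JASPAR raw/pfm text: records of a `>ID NAME` header followed by
#' four base rows, either `A [ 4 19 0 ]` style or bare numbers in A, C, G,
#' T order.  Count matrices are smoothed with `pseudocount` per cell and
#' column-normalized; matrices whose columns already sum to 1 are accepted
#' as probabilities unchanged.
#'
#' @param path Path to the pfm file.
#' @param pseudocount Count added to every cell before normalization
#'   (default 1).
#' @param background Base composition for log-odds scoring (default
#'   uniform).
#' @return A named list of `pwm` objects.
#' @export
read_pwms_jaspar <- function(path, pseudocount = 1,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) abort("no '>' record headers found")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (h in seq_along(heads)) {
    block <- lines[(bounds[h] + 1L):(bounds[h + 1L] - 1L)]
    if (length(block) != 4L) {
      abort(sprintf("record %d: expected 4 matrix rows, got %d",
                    h, length(block)))
    }
    header <- sub("^>\\s*", "", lines[heads[h]])
    toks <- strsplit(header, "\\s+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else id

    labelled <- grepl("^[ACGTacgt]", trimws(block))
    rows <- lapply(block, function(ln) {
      ln <- gsub("[][]", " ", ln)
      ln <- sub("^\\s*[ACGTacgt]\\s*", " ", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    if (all(labelled)) {
      base_of <- toupper(substr(trimws(block), 1L, 1L))
      if (!setequal(base_of, BASES)) {
        abort(sprintf("record %s: need one row per base A,C,G,T; got %s",
                      id, paste(base_of, collapse = ",")))
      }
      rows <- rows[match(BASES, base_of)]
    }
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      abort(sprintf("record %s: rows of unequal width (%s)",
                    id, paste(widths, collapse = ",")))
    }
    m <- do.call(rbind, rows)
    if (any(m < 0)) abort(sprintf("record %s: negative counts", id))
    colsum <- colSums(m)
    if (all(abs(colsum - 1) < 1e-6)) {
      probs <- m  # already probabilities; accept unchanged
    } else {
      probs <- sweep(m + pseudocount, 2L, colsum + 4 * pseudocount, "/")
    }
    out[[id]] <- new_pwm(id, name, probs, background[BASES])
  }
  out
}

#' Log-odds score of a sequence under a PWM
#'
#' `sum_i log2(p_i(base_i) / bg(base_i))`, in bits.  The sequence length
#' must equal the motif width; any base outside A/C/G/T gives NA.
#'
#' @param pwm A `pwm` object.
#' @param sequence A character string of length equal to the motif width.
#' @return Log-odds score in bits (or NA).
#' @export
pwm_score <- function(pwm, sequence) {
  w <- ncol(pwm$probs)
  stopifnot(nchar(sequence) == w)
  b <- strsplit(toupper(sequence), "")[[1]]
  i <- match(b, BASES)
  if (anyNA(i)) return(NA_real_)
  sum(log2(pwm$probs[cbind(i, seq_len(w))] / pwm$background[i]))
}

#' Score range of a PWM
#'
#' @param pwm A `pwm` object.
#' @return Named vector `c(min, max)` of the attainable log-odds range.
#' @export
pwm_score_range <- function(pwm) {
  lo <- log2(sweep(pwm$probs, 1L, pwm$background, "/"))
  c(min = sum(apply(lo, 2L, min)), max = sum(apply(lo, 2L, max)))
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", s), "")[[1]]),
        collapse = "")
}

best_pwm_match <- function(pwm, flank, snp_offset) {
  w <- ncol(pwm$probs)
  best <- list(score = -Inf, strand = NA_character_, offset = NA_integer_)
  for (start in (snp_offset - w + 1L):snp_offset) {
    s <- substr(flank, start, start + w - 1L)
    for (strand in c("+", "-")) {
      sc <- pwm_score(pwm, if (strand == "+") s else revcomp(s))
      if (!is.na(sc) && sc > best$score) {
        best <- list(score = sc, strand = strand, offset = start)
      }
    }
  }
  if (!is.finite(best$score)) best$score <- NA_real_
  best
}

#' Call a TFBS alteration for a SNP under one PWM
#'
#' Both alleles are scored as the best log-odds match over every motif
#' window overlapping the SNP, on both strands.  An allele is a *hit* when
#' its best score reaches `min + hit_fraction * (max - min)` of the PWM's
#' attainable score range.  The call is `loss` (ref hit, alt not), `gain`
#' (alt hit, ref not), `change` (both hit, score difference above
#' `change_min_delta`), or `none`.
#'
#' @param flank Reference-allele sequence context around the SNP; must
#'   extend at least `width - 1` bases on both sides of the SNP.
#' @param snp_offset 1-based position of the SNP within `flank`.
#' @param ref,alt SNP alleles; `flank` must carry `ref` at `snp_offset`.
#' @param pwm A `pwm` object.
#' @param hit_fraction Fraction of the score range for a hit (default 0.8).
#' @param change_min_delta Minimum |ref - alt| score difference (bits) for
#'   a both-hit `change` call (default 0).
#' @return A one-row tibble: `tf`, `ref_score`, `alt_score`, `delta`,
#'   `threshold`, `strand`, `offset`, `call`.
#' @export
tfbs_alteration_call <- function(flank, snp_offset, ref, alt, pwm,
                                 hit_fraction = 0.8, change_min_delta = 0) {
  w <- ncol(pwm$probs)
  if (snp_offset - (w - 1L) < 1L ||
      snp_offset + (w - 1L) > nchar(flank)) {
    abort(sprintf("flank too short: need %d bases on both sides of the SNP",
                  w - 1L))
  }
  if (toupper(substr(flank, snp_offset, snp_offset)) != toupper(ref)) {
    abort(sprintf("flank carries '%s' at the SNP offset, expected ref '%s'",
                  substr(flank, snp_offset, snp_offset), ref))
  }
  alt_flank <- flank
  substr(alt_flank, snp_offset, snp_offset) <- alt

  best_ref <- best_pwm_match(pwm, flank, snp_offset)
  best_alt <- best_pwm_match(pwm, alt_flank, snp_offset)
  rng <- pwm_score_range(pwm)
  threshold <- rng["min"] + hit_fraction * (rng["max"] - rng["min"])

  ref_hit <- !is.na(best_ref$score) && best_ref$score >= threshold
  alt_hit <- !is.na(best_alt$score) && best_alt$score >= threshold
  delta <- best_ref$score - best_alt$score
  call <- if (ref_hit && !alt_hit) "loss"
          else if (!ref_hit && alt_hit) "gain"
          else if (ref_hit && alt_hit &&
                   !is.na(delta) && abs(delta) > change_min_delta) "change"
          else "none"
  tibble(
    tf = pwm$id,
    ref_score = best_ref$score, alt_score = best_alt$score,
    delta = delta, threshold = unname(threshold),
    strand = best_ref$strand, offset = best_ref$offset,
    call = call
  )
}
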