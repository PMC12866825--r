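#' Pair BS and ACE tracks on shared CpG sites
#'
#' Keeps only CpG positions present in both assays with coverage at
#' least `min_cov` in each; ordering is preserved.
#'
#' @param bs,ace Count [methylome_track()]s for the same sample on the
#'   same genome (BS signal = 5mC + 5hmC; ACE signal = 5hmC).
#' @param min_cov Minimum coverage per assay (reads).
#' @return data.frame with columns `chrom`, `pos`, `n_bs`, `k_bs`,
#'   `n_ace`, `k_ace`.
#' @export
intersect_sites <- function(bs, ace, min_cov = 3) {
  a <- as.data.frame(bs); b <- as.data.frame(ace)
  shared_chroms <- union(a$chrom, b$chrom)
  if (nrow(a) && nrow(b) &&
      !length(intersect(unique(a$chrom), unique(b$chrom))) &&
      length(shared_chroms))
    stop("BS and ACE tracks share no chromosome names; ",
         "mismatched chromosome namespaces?")
  key_a <- paste(a$chrom, a$pos)
  key_b <- paste(b$chrom, b$pos)
  idx <- match(key_a, key_b)
  keep <- !is.na(idx)
  out <- data.frame(chrom = a$chrom[keep], pos = a$pos[keep],
                    n_bs = a$n[keep], k_bs = a$k[keep],
                    n_ace = b$n[idx[keep]], k_ace = b$k[idx[keep]])
  out[out$n_bs >= min_cov & out$n_ace >= min_cov, , drop = FALSE]
}

#' Constrained MLE of (u, 5mC, 5hmC) from paired BS/ACE counts
#'
#' At each CpG, the BS non-conversion probability is `m + h` and the
#' ACE non-conversion probability is `h`. The joint likelihood
#' `Binom(k_bs; n_bs, m + h) * Binom(k_ace; n_ace, h)` is maximised over
#' the simplex `m, h >= 0`, `m + h <= 1`. When the unconstrained
#' estimate `m = k_bs/n_bs - k_ace/n_ace` is non-negative the interior
#' solution is returned; otherwise the maximum lies on the boundary
#' `m = 0` with the pooled estimate `h = (k_bs + k_ace)/(n_bs + n_ace)`,
#' and the site is flagged as a conflict.
#'
#' @param k_bs,n_bs,k_ace,n_ace Vectors of non-converted counts and
#'   coverages (recycled to common length); coverages must be >= 1.
#' @return data.frame with columns `u`, `m`, `h` (summing to 1) and
#'   `conflict`.
#' @export
mle_decompose <- function(k_bs, n_bs, k_ace, n_ace) {
  len <- max(length(k_bs), length(n_bs), length(k_ace), length(n_ace))
  k_bs <- rep_len(k_bs, len); n_bs <- rep_len(n_bs, len)
  k_ace <- rep_len(k_ace, len); n_ace <- rep_len(n_ace, len)
  if (any(n_bs < 1) || any(n_ace < 1))
    stop("mle_decompose requires coverage >= 1 in both assays")
  if (any(k_bs < 0 | k_bs > n_bs | k_ace < 0 | k_ace > n_ace))
    stop("counts must satisfy 0 <= k <= n")
  p_bs <- k_bs / n_bs
  p_ace <- k_ace / n_ace
  conflict <- p_bs < p_ace
  h <- ifelse(conflict, (k_bs + k_ace) / (n_bs + n_ace), p_ace)
  m <- ifelse(conflict, 0, p_bs - p_ace)
  u <- 1 - m - h
  ## guard against floating-point drift off the simplex
  u <- pmin(pmax(u, 0), 1)
  s <- u + m + h
  data.frame(u = u / s, m = m / s, h = h / s, conflict = conflict)
}

#' Decompose a paired sample into 5mC and 5hmC level tracks
#'
#' Runs [intersect_sites()] and [mle_decompose()] and splits the result
#' into `level_m` and `level_h` tracks. Conflicted sites (negative
#' unconstrained 5mC) are filtered out by default, mirroring the
#' practice of discarding sites with negative levels or conflicts;
#' `filter_conflicts = FALSE` retains their boundary estimates with the
#' flag set.
#'
#' @inheritParams intersect_sites
#' @param filter_conflicts Drop conflicted sites from the level tracks?
#' @return list with `level_m` and `level_h` [methylome_track()]s (each
#'   carrying a `weight` column with the summed coverage), the per-site
#'   `sites` decomposition table, `conflict_fraction`, and counts
#'   `n_paired` / `n_skipped` (zero-coverage sites dropped at pairing).
#' @export
decompose_track <- function(bs, ace, min_cov = 3, filter_conflicts = TRUE) {
  meta <- attr(bs, "meta")
  paired_all <- intersect_sites(bs, ace, min_cov = 0)
  usable <- paired_all$n_bs >= pmax(min_cov, 1) &
    paired_all$n_ace >= pmax(min_cov, 1)
  n_skipped <- sum(!usable)
  if (n_skipped)
    message("decompose_track: skipped ", n_skipped,
            " paired sites below coverage ", max(min_cov, 1))
  paired <- paired_all[usable, , drop = FALSE]
  est <- mle_decompose(paired$k_bs, paired$n_bs, paired$k_ace, paired$n_ace)
  sites <- cbind(paired[, c("chrom", "pos")], est,
                 paired[, c("n_bs", "k_bs", "n_ace", "k_ace")])
  conflict_fraction <- if (nrow(sites)) mean(sites$conflict) else NA_real_
  keep <- if (filter_conflicts) !sites$conflict else rep(TRUE, nrow(sites))
  kept <- sites[keep, , drop = FALSE]
  w <- kept$n_bs + kept$n_ace
  mk_level <- function(level, state) {
    methylome_track(
      data.frame(chrom = kept$chrom, pos = kept$pos, level = level,
                 weight = w),
      meta, state)
  }
  list(level_m = mk_level(kept$m, "level_m"),
       level_h = mk_level(kept$h, "level_h"),
       sites = sites,
       conflict_fraction = conflict_fraction,
       n_paired = nrow(sites), n_skipped = n_skipped)
}
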