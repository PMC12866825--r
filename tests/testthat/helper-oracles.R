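# Independent reference implementations used to pin the package's
# analytical code. Each oracle recomputes its quantity by direct
# enumeration / brute force, never by calling the code path it checks.

# Grid-search maximizer of the joint binomial log-likelihood over the
# (m, h) simplex, parameterised as p1 = m + h, p2 = h with p2 <= p1.
# For each p1 the best p2 is found by prefix-argmax of the ACE
# log-likelihood, so a fine grid stays cheap.
oracle_mle_grid <- function(k_bs, n_bs, k_ace, n_ace, step = 1e-4) {
  p <- seq(0, 1, by = step)
  ll_of <- function(k, n) {
    ll <- k * log(p) + (n - k) * log1p(-p)
    ll[p == 0] <- if (k == 0) 0 else -Inf
    ll[p == 1] <- if (k == n) 0 else -Inf
    ll
  }
  ll1 <- ll_of(k_bs, n_bs)
  ll2 <- ll_of(k_ace, n_ace)
  # best2[j] = index i <= j maximizing ll2[i]
  best2 <- integer(length(p))
  best2[1] <- 1L
  for (j in 2:length(p))
    best2[j] <- if (ll2[j] > ll2[best2[j - 1]]) j else best2[j - 1]
  tot <- ll1 + ll2[best2]
  j <- which.max(tot)
  h <- p[best2[j]]
  c(m = p[j] - h, h = h)
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric
# enumeration: sum the probabilities of all tables (with the observed
# margins) no more probable than the observed one.
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Equal-variance two-sample t p-value via stats::t.test, with the
# caller's degenerate-window convention.
oracle_t_p <- function(xa, xb) {
  if (length(xa) < 2 || length(xb) < 2) return(NA_real_)
  if (stats::var(xa) == 0 && stats::var(xb) == 0)
    return(if (abs(mean(xa) - mean(xb)) <= 1e-12) 1 else 0)
  stats::t.test(xa, xb, var.equal = TRUE)$p.value
}

# Direct re-enumeration of the whole differential caller on a paired
# site table: plain loops over tiles, windows, merges and classes.
oracle_call_dmrs <- function(sites, genome, params) {
  # tiles with >= min_cpg_tile sites
  tiles <- list()
  for (cn in unique(sites$chrom)) {
    s <- sites[sites$chrom == cn, ]
    for (tl in unique(floor(s$pos / params$tile_bp))) {
      n_in <- sum(floor(s$pos / params$tile_bp) == tl)
      if (n_in >= params$min_cpg_tile)
        tiles[[length(tiles) + 1]] <-
          data.frame(chrom = cn, start = tl * params$tile_bp,
                     end = min((tl + 1) * params$tile_bp,
                               genome$chrom_sizes[[cn]]))
    }
  }
  tiles <- if (length(tiles)) do.call(rbind, tiles) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  visible <- sites[rep(FALSE, nrow(sites)), ]
  for (i in seq_len(nrow(tiles)))
    visible <- rbind(visible,
                     sites[sites$chrom == tiles$chrom[i] &
                             sites$pos >= tiles$start[i] &
                             sites$pos < tiles$end[i], ])
  visible <- visible[order(visible$chrom, visible$pos), ]
  # sliding windows
  wins <- list()
  for (cn in unique(visible$chrom)) {
    s <- visible[visible$chrom == cn, ]
    sz <- genome$chrom_sizes[[cn]]
    for (st in seq(0, max(0, sz - 1), by = params$step_bp)) {
      en <- min(st + params$window_bp, sz)
      inw <- s$pos >= st & s$pos < en
      if (sum(inw) < 2) next
      p <- oracle_t_p(s$la[inw], s$lb[inw])
      wins[[length(wins) + 1]] <-
        data.frame(chrom = cn, start = st, end = en, p = p)
    }
  }
  if (!length(wins)) return(data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    region_class = character(), n_cpg = integer(), p = numeric(),
    q = numeric()))
  wins <- do.call(rbind, wins)
  # merge overlapping significant windows
  sig <- wins[wins$p < params$merge_p, ]
  regions <- list()
  for (cn in unique(sig$chrom)) {
    s <- sig[sig$chrom == cn, ]
    s <- s[order(s$start), ]
    cur <- c(s$start[1], s$end[1])
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] < cur[2]) cur[2] <- max(cur[2], s$end[i])
      else { regions[[length(regions) + 1]] <- c(cn, cur)
             cur <- c(s$start[i], s$end[i]) }
    }
    regions[[length(regions) + 1]] <- c(cn, cur)
  }
  if (!length(regions)) return(data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    region_class = character(), n_cpg = integer(), p = numeric(),
    q = numeric()))
  reg <- data.frame(chrom = sapply(regions, `[`, 1),
                    start = as.numeric(sapply(regions, `[`, 2)),
                    end = as.numeric(sapply(regions, `[`, 3)))
  score <- function(reg) {
    for (i in seq_len(nrow(reg))) {
      inr <- visible$chrom == reg$chrom[i] &
        visible$pos >= reg$start[i] & visible$pos < reg$end[i]
      reg$mean_a[i] <- mean(visible$la[inr])
      reg$mean_b[i] <- mean(visible$lb[inr])
      reg$p[i] <- oracle_t_p(visible$la[inr], visible$lb[inr])
      reg$n_cpg[i] <- sum(inr)
    }
    reg$diff <- reg$mean_a - reg$mean_b
    reg
  }
  classify <- function(reg) {
    for (i in seq_len(nrow(reg))) {
      d <- reg$diff[i]
      cls <- "none"
      if (d > params$diff_hyper) cls <- "hyper"
      else if (d < -params$diff_hyper) cls <- "hypo"
      else if (abs(d) < params$stable_diff &&
               reg$mean_a[i] > params$stable_floor &&
               reg$mean_b[i] > params$stable_floor) cls <- "stable_high"
      else if (params$mode == "hydroxymethylation" &&
               abs(d) < params$stable_diff &&
               reg$mean_a[i] <= params$stable_floor &&
               reg$mean_b[i] <= params$stable_floor) cls <- "stable_low"
      reg$region_class[i] <- cls
    }
    reg
  }
  reg <- classify(score(reg))
  # same-class merge within gap
  merged <- list()
  for (key in unique(paste(reg$chrom, reg$region_class))) {
    s <- reg[paste(reg$chrom, reg$region_class) == key, ]
    s <- s[order(s$start), ]
    cur <- c(s$start[1], s$end[1])
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] - cur[2] <= params$same_class_gap)
        cur[2] <- max(cur[2], s$end[i])
      else { merged[[length(merged) + 1]] <-
               data.frame(chrom = s$chrom[1], start = cur[1],
                          end = cur[2], region_class = s$region_class[1])
             cur <- c(s$start[i], s$end[i]) }
    }
    merged[[length(merged) + 1]] <-
      data.frame(chrom = s$chrom[1], start = cur[1], end = cur[2],
                 region_class = s$region_class[1])
  }
  reg2 <- do.call(rbind, merged)
  reg2 <- reg2[order(reg2$chrom, reg2$start), ]
  cls <- reg2$region_class
  reg2 <- score(reg2[, c("chrom", "start", "end")])
  reg2$region_class <- cls
  # BH over candidates, retention rules
  reg2$q <- stats::p.adjust(reg2$p, method = "BH")
  keep <- (reg2$region_class %in% c("hyper", "hypo") &
             reg2$n_cpg >= params$min_cpg_region &
             reg2$q < params$region_q) |
    (reg2$region_class %in% c("stable_high", "stable_low") &
       reg2$q > params$stable_q)
  out <- reg2[keep, ]
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# fraction of planted regions recovered by called regions at a
# reciprocal-overlap threshold
recovered_fraction <- function(planted, called, min_reciprocal = 0.5) {
  if (!nrow(called)) return(0)
  hit <- logical(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    ov <- pmax(0, pmin(planted$end[i], called$end) -
                 pmax(planted$start[i], called$start))
    ov[called$chrom != planted$chrom[i]] <- 0
    rec <- ov / (planted$end[i] - planted$start[i])
    rec2 <- ov / (called$end - called$start)
    hit[i] <- any(rec >= min_reciprocal & rec2 >= min_reciprocal)
  }
  mean(hit)
}
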