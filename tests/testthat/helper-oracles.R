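# Independent brute-force oracles used against the package implementations.

# Exact Wilcoxon signed-rank: V and two-sided p by enumerating all 2^n sign
# assignments (assumes no zeros and no tied |x|).
oracle_signed_rank <- function(x) {
  n <- length(x)
  stopifnot(n <= 14, all(x != 0), !anyDuplicated(abs(x)))
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.numeric(signs %*% r)
  p <- min(1, 2 * min(mean(v_null <= v_obs), mean(v_null >= v_obs)))
  list(statistic = v_obs, p_two_sided = p)
}

# Exact Mann-Whitney: W (= number of (x, y) pairs with x > y, R's statistic
# for wilcox.test(x, y)) and exact p by enumerating all group reassignments.
oracle_mann_whitney <- function(x, y) {
  n <- length(x)
  m <- length(y)
  pool <- c(x, y)
  stopifnot(choose(n + m, n) <= 5e4, !anyDuplicated(pool))
  w_of <- function(a, b) sum(outer(a, b, ">"))
  w_obs <- w_of(x, y)
  combos <- utils::combn(n + m, n)
  w_null <- apply(combos, 2, function(i) w_of(pool[i], pool[-i]))
  p_two <- min(1, 2 * min(mean(w_null <= w_obs), mean(w_null >= w_obs)))
  p_greater <- mean(w_null >= w_obs)
  list(statistic = w_obs, p_two_sided = p_two, p_greater = p_greater)
}

# Step-by-step weighted Kolmogorov-Smirnov running sum, written as an
# explicit loop.
oracle_es <- function(ranking, set, weight = 1) {
  ord <- order(ranking, decreasing = TRUE)
  ids <- names(ranking)[ord]
  vals <- ranking[ord]
  hit_w <- numeric(length(ids))
  for (i in seq_along(ids)) {
    if (ids[i] %in% set) hit_w[i] <- abs(vals[i])^weight
  }
  n <- sum(ids %in% set)
  run <- numeric(length(ids))
  acc <- 0
  denom <- sum(hit_w)
  for (i in seq_along(ids)) {
    if (ids[i] %in% set) {
      acc <- acc + (if (denom > 0) hit_w[i] / denom else 1 / n)
    } else {
      acc <- acc - 1 / (length(ids) - n)
    }
    run[i] <- acc
  }
  run[which.max(abs(run))]
}

# Two-pass TPM, one explicit loop per sample.
oracle_tpm <- function(counts, lengths) {
  out <- counts * 0
  for (j in seq_len(ncol(counts))) {
    rate <- numeric(nrow(counts))
    for (i in seq_len(nrow(counts))) rate[i] <- counts[i, j] / lengths[i]
    out[, j] <- rate / sum(rate) * 1e6
  }
  out
}

# Trapezoidal window integration written independently (explicit loop with
# boundary interpolation), mirroring the P/M definition.
oracle_window_ratio <- function(trace) {
  x <- trace$position
  y <- trace$absorbance - min(trace$absorbance)
  interp <- function(x0) {
    i <- max(which(x <= x0))
    if (x[i] == x0) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (x0 - x[i]) / (x[i + 1] - x[i])
  }
  win_area <- function(lo, hi) {
    xs <- c(lo, x[x > lo & x < hi], hi)
    ys <- c(interp(lo), y[x > lo & x < hi], interp(hi))
    a <- 0
    for (i in seq_len(length(xs) - 1)) {
      a <- a + (xs[i + 1] - xs[i]) * (ys[i] + ys[i + 1]) / 2
    }
    a
  }
  b <- trace$boundaries
  win_area(b$poly_start, b$poly_end) / win_area(b$mono_start, b$mono_end)
}

# A small hand-built tRNA reference: `n` species, the first `n_mod` carrying
# G46 in an AGGUC context, the rest with A at 46.
tiny_reference <- function(n = 6, n_mod = 2, seed = 42) {
  withr::with_seed(seed, {
    acs <- c("AGG", "AAC", "CUG", "GAA", "UGG", "GUA", "CAU", "UCU")
    aas <- c("Pro", "Val", "Gln", "Phe", "Pro", "Tyr", "Met", "Arg")
    k <- (seq_len(n) - 1) %% length(acs) + 1
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(c("A", "C", "G", "U"), 73, replace = TRUE)
      s[34:36] <- strsplit(acs[k[i]], "")[[1]]
      if (i <= n_mod) s[44:48] <- c("A", "G", "G", "U", "C") else s[46] <- "A"
      paste(c(s, "C", "C", "A"), collapse = "")
    }, character(1))
    trna_reference(paste0(aas[k], "-", acs[k], "-", seq_len(n)), seqs)
  })
}

# Small pileup for one tRNA/library from explicit count vectors.
make_profile <- function(trna_id, coverage, term, sample_id = "s1",
                         condition = "treated") {
  data.frame(trna_id = trna_id, position = seq_along(coverage),
             coverage = coverage, term = term, sample_id = sample_id,
             condition = condition, stringsAsFactors = FALSE)
}
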