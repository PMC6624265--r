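# Independent brute-force references. These are deliberately written as
# plain scalar loops with their own arithmetic, so they share no code path
# with the package implementations they check.

# two-sided Fisher p by direct enumeration with choose()
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  denom <- choose(N, k)
  p_obs <- choose(m, a) * choose(n, k - a) / denom
  tot <- 0
  for (x in max(0, k - n):min(k, m)) {
    px <- choose(m, x) * choose(n, k - x) / denom
    if (px <= p_obs * (1 + 1e-7)) tot <- tot + px
  }
  min(1, tot)
}

# BH step-up by explicit sorting
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# single-group beta-binomial moment statistics, scalar version
.oracle_group <- function(ms, ns, rho_floor = 1e-3) {
  keep <- ns > 0
  ms <- ms[keep]; ns <- ns[keep]
  N <- sum(ns); R <- length(ns)
  if (N == 0) return(NULL)
  ph <- sum(ms) / N
  S <- 0
  for (r in seq_len(R)) S <- S + ns[r] * (ms[r] / ns[r] - ph)^2
  pq <- max(ph * (1 - ph), 1e-8)
  den <- N - R - (sum(ns^2) - N) / N
  rho <- (S / pq - (R - 1)) / max(den, 1e-8)
  rho <- min(max(rho, rho_floor), 0.99)
  v <- 0
  for (r in seq_len(R)) v <- v + ns[r] * (1 + (ns[r] - 1) * rho)
  list(mu = ph, var = ph * (1 - ph) * v / N^2)
}

# full per-base DMC -> stitch -> filter -> classify reference (biological
# replicates); positions are assumed shared across all tables
oracle_dmr_path <- function(pgc, soma, repeats, alpha = 1e-3, max_gap = 50,
                            min_dmc = 5, min_span = 50, low_cov = 5,
                            max_lowfrac = 0.25, min_delta = 0.1) {
  pos <- sort(unique(unlist(lapply(c(pgc, soma), function(t) t$pos))))
  get <- function(tab, p, col) {
    i <- match(p, tab$pos)
    if (is.na(i)) 0 else tab[[col]][i]
  }
  dmc <- logical(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    g1 <- .oracle_group(vapply(pgc, get, numeric(1), p = p, col = "count_M"),
                        vapply(pgc, function(t)
                          get(t, p, "count_M") + get(t, p, "count_U"),
                          numeric(1)))
    g2 <- .oracle_group(vapply(soma, get, numeric(1), p = p, col = "count_M"),
                        vapply(soma, function(t)
                          get(t, p, "count_M") + get(t, p, "count_U"),
                          numeric(1)))
    if (is.null(g1) || is.null(g2)) next
    d <- g1$mu - g2$mu
    v <- g1$var + g2$var
    pval <- if (v > 0) 2 * pnorm(-abs(d) / sqrt(v)) else if (d == 0) 1 else 0
    dmc[i] <- pval < alpha
  }
  hits <- pos[dmc]
  out <- list()
  i <- 1
  while (i <= length(hits)) {
    j <- i
    while (j < length(hits) && hits[j + 1] - hits[j] <= max_gap) j <- j + 1
    run <- hits[i:j]
    i <- j + 1
    if (length(run) < min_dmc) next
    start <- run[1] - 1; end <- run[length(run)]
    if (end - start < min_span) next
    in_rep <- FALSE
    if (nrow(repeats))
      for (r in seq_len(nrow(repeats)))
        if (repeats$start[r] < end && repeats$end[r] > start) in_rep <- TRUE
    if (in_rep) next
    inside <- pos[pos > start & pos <= end]
    n_low <- 0
    for (p in inside) {
      c1 <- sum(vapply(pgc, function(t)
        get(t, p, "count_M") + get(t, p, "count_U"), numeric(1)))
      c2 <- sum(vapply(soma, function(t)
        get(t, p, "count_M") + get(t, p, "count_U"), numeric(1)))
      if (c1 < low_cov || c2 < low_cov) n_low <- n_low + 1
    }
    if (n_low / length(inside) > max_lowfrac) next
    deltas <- vapply(seq_along(pgc), function(r) {
      m1 <- sum(vapply(inside, get, numeric(1), tab = pgc[[r]],
                       col = "count_M"))
      n1 <- m1 + sum(vapply(inside, get, numeric(1), tab = pgc[[r]],
                            col = "count_U"))
      m2 <- sum(vapply(inside, get, numeric(1), tab = soma[[r]],
                       col = "count_M"))
      n2 <- m2 + sum(vapply(inside, get, numeric(1), tab = soma[[r]],
                            col = "count_U"))
      if (n1 == 0 || n2 == 0) return(NA_real_)
      m1 / n1 - m2 / n2
    }, numeric(1))
    cls <- if (!anyNA(deltas) && all(deltas <= -min_delta)) "hypo_in_PGC"
    else if (!anyNA(deltas) && all(deltas >= min_delta)) "hyper_in_PGC"
    else "unclassified"
    out[[length(out) + 1]] <-
      data.frame(start = start, end = end, n_dmc = length(run), class = cls,
                 stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), n_dmc = integer(),
                      class = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# random single-chromosome instance for the DMR-path property test
random_dmr_instance <- function(seed) {
  set.seed(seed)
  n_cpg <- sample(20:200, 1)
  # mixed spacing so runs both form and break
  pos <- cumsum(sample(c(2:30, 60:120), n_cpg, replace = TRUE,
                       prob = c(rep(4, 29), rep(1, 61))))
  make <- function(mu) {
    cov <- pmax(1L, rnbinom(n_cpg, mu = 12, size = 5))
    data.frame(chrom = "chr1", pos = pos,
               count_M = rbinom(n_cpg, cov, mu), count_U = 0L,
               stringsAsFactors = FALSE) -> t
    t$count_U <- cov - t$count_M
    t
  }
  # piecewise means create genuine DMC runs in part of the instance
  mu1 <- ifelse(seq_len(n_cpg) %% 7 < 3, 0.15, 0.8)
  mu2 <- rep(0.8, n_cpg)
  pgc <- list(make(mu1), make(mu1))
  soma <- list(make(mu2), make(mu2))
  reps <- if (runif(1) < 0.5) {
    st <- sample(max(pos), 2)
    region_set("chr1", st, st + sample(50:200, 2, replace = TRUE))
  } else region_set()
  list(pgc = pgc, soma = soma, repeats = reps)
}

# splicing rule evaluator, scalar loops
oracle_diff_exons <- function(psi, cols_a, cols_b, min_avg = 15,
                              min_pair = 5) {
  out <- logical(nrow(psi))
  for (i in seq_len(nrow(psi))) {
    d1 <- psi[i, cols_a[1]] - psi[i, cols_b[1]]
    d2 <- psi[i, cols_a[2]] - psi[i, cols_b[2]]
    out[i] <- abs((d1 + d2) / 2) >= min_avg && abs(d1) >= min_pair &&
      abs(d2) >= min_pair && sign(d1) == sign(d2) && sign(d1) != 0
  }
  out
}
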