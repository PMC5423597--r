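# Independent oracles: deliberately naive implementations used only to
# cross-check the package's fast paths. They must stay free of any code
# from R/.

# two-sided minimum-likelihood Fisher p by explicit table enumeration,
# probabilities from log-factorials (no dhyper)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  lp <- vapply(lo:hi, function(x)
    lgamma(m + 1) - lgamma(x + 1) - lgamma(m - x + 1) +
      lgamma(n + 1) - lgamma(k - x + 1) - lgamma(n - k + x + 1) -
      (lgamma(m + n + 1) - lgamma(k + 1) - lgamma(m + n - k + 1)),
    0)
  p <- exp(lp)
  p_obs <- p[a - lo + 1]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# O(n*m) pairwise half-open interval overlap
oracle_overlap <- function(segments, genes) {
  out <- list(); k <- 0
  for (i in seq_len(nrow(segments))) {
    for (j in seq_len(nrow(genes))) {
      if (segments$chrom[i] == genes$chrom[j] &&
          segments$start_bp[i] < genes$end_bp[j] &&
          genes$start_bp[j] < segments$end_bp[i]) {
        k <- k + 1
        out[[k]] <- data.frame(sample_id = segments$sample_id[i],
                               symbol = genes$symbol[j],
                               state = segments$state[i],
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0) return(data.frame(sample_id = character(),
                                symbol = character(),
                                state = character()))
  unique(do.call(rbind, out))
}

# naive UPGMA over a feature matrix: returns sorted merge heights
oracle_upgma_heights <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best[1]) best <- c(dij, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# hand-rolled product-limit estimator
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = tt, surv = NA_real_)
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    died <- sum(time == tt[i] & event)
    s <- s * (1 - died / at_risk)
    out$surv[i] <- s
  }
  out
}

oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Breslow log partial likelihood of a two-group Cox model at log-HR beta
oracle_breslow_loglik <- function(beta, time, event, g1) {
  ll <- 0
  for (t in sort(unique(time[event]))) {
    dead <- which(time == t & event)
    risk <- which(time >= t)
    ll <- ll + beta * sum(g1[dead]) -
      length(dead) * log(sum(exp(beta * g1[risk])))
  }
  ll
}

oracle_cox_grid <- function(time, event, g1, grid = seq(-5, 5, 0.001)) {
  ll <- vapply(grid, oracle_breslow_loglik, 0, time = time, event = event,
               g1 = g1)
  grid[which.max(ll)]
}

# vectorised logrank statistic for B label permutations; returns the
# permutation p-value of the observed labels
oracle_logrank_perm_p <- function(time, event, g1, B = 10000, seed = 1) {
  set.seed(seed)
  stat <- function(g) {
    o <- 0; e <- 0; v <- 0
    for (t in sort(unique(time[event]))) {
      risk <- time >= t
      d <- sum(time == t & event)
      n <- sum(risk); n1 <- sum(risk & g)
      o <- o + sum(time == t & event & g)
      e <- e + d * n1 / n
      if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (o - e)^2 / v
  }
  obs <- stat(g1)
  perms <- replicate(B, stat(sample(g1)))
  mean(perms >= obs - 1e-12)
}
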