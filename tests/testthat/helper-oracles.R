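# Independent brute-force oracles used to check the implementations.
# Everything here is written naively (explicit loops, textbook formulas)
# and never calls the package's own primitives.

# Breslow partial log-likelihood for one covariate, direct double loop
oracleBreslowLoglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    deaths <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[deaths]) -
      length(deaths) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# golden-section maximization of a unimodal function on [lo, hi]
goldenSectionMax <- function(f, lo, hi, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  (a + b) / 2
}

# spreadsheet-style product-limit computation
oracleKm <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = et, survival = NA_real_)
  for (i in seq_along(et)) {
    at_risk <- sum(time >= et[i])
    d <- sum(time == et[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# explicit O-E / V accumulation for the two-group log-rank statistic
oracleLogrank <- function(time, event, group) {
  lev <- sort(unique(group))
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    n <- sum(risk); n1 <- sum(risk & group == lev[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lev[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * n1 / n * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# naive per-sample ssGSEA running sum for one set
oracleSsgseaOne <- function(x, set_genes, alpha) {
  genes <- names(x)
  ord <- order(x, decreasing = TRUE)
  r <- rank(x, ties.method = "average")
  N <- length(x)
  in_set <- genes %in% set_genes
  denom_in <- sum(r[in_set]^alpha)
  n_out <- N - sum(in_set)
  p_in <- p_out <- 0
  es <- 0
  for (i in seq_len(N)) {
    g <- ord[i]
    if (in_set[g]) p_in <- p_in + r[g]^alpha / denom_in
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# pairwise-enumeration AUC: wins + half ties over all positive x negative
oracleAuc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracleRankSumP <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  ws <- apply(combs, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# IPCW time-dependent AUC by explicit weighted double loop; censoring
# survival computed by its own product-limit loop
oracleTdAuc <- function(scores, time, event, horizon) {
  cens_surv <- function(tt, strict) {
    s <- 1
    for (u in sort(unique(time[event == 0]))) {
      if ((strict && u < tt) || (!strict && u <= tt)) {
        at_risk <- sum(time >= u)
        d <- sum(time == u & event == 0)
        s <- s * (1 - d / at_risk)
      }
    }
    s
  }
  cases <- which(time <= horizon & event == 1)
  ctrls <- which(time > horizon)
  num <- den <- 0
  for (i in cases) {
    wi <- 1 / cens_surv(time[i], strict = TRUE)
    for (j in ctrls) {
      wj <- 1 / cens_surv(horizon, strict = FALSE)
      cmp <- if (scores[i] > scores[j]) 1
        else if (scores[i] == scores[j]) 0.5 else 0
      num <- num + wi * wj * cmp
      den <- den + wi * wj
    }
  }
  num / den
}

# small toy cohort with fixed, hand-readable numbers
toyCohort <- function(name = "toy") {
  expr <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8,
                   8, 7, 6, 5, 4, 3, 2, 1,
                   2, 2, 2, 2, 9, 9, 9, 9), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:8)))
  clin <- data.frame(sample_id = paste0("s", 1:8),
                     os_time = c(5, 8, 12, 20, 3, 9, 15, 30),
                     os_event = c(1, 1, 0, 1, 1, 0, 1, 1))
  Cohort(expr, clin, name = name)
}

# deterministic random survival dataset generator for oracle sweeps;
# continuous times are almost surely tie-free, so the classical score-test /
# log-rank equivalence holds exactly
randomSurvData <- function(n, seed) {
  set.seed(seed)
  list(time = rexp(n, 0.1) + 0.1,
       event = rbinom(n, 1, 0.7),
       x = rbinom(n, 1, 0.5))
}
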