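# Survival-analysis primitives: product-limit estimator, two-group
# log-rank, Cox partial likelihood (Breslow ties, Newton-Raphson), and the
# IPCW cumulative/dynamic time-dependent AUC.

checkSurv <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be finite and positive")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicators (1 = death/relapse observed).
#' @return data.frame of class `"kmEstimate"` with one row per distinct
#'   event time: `time`, `n_risk`, `n_event`, `survival` (the product-limit
#'   estimate just after `time`). `S(0) = 1`; the curve is right-continuous
#'   and non-increasing. With no events the estimate is identically 1.
#' @examples
#' kmEstimate(c(6, 6, 7, 9, 11, 12), c(1, 1, 0, 1, 0, 1))
#' @export
kmEstimate <- function(time, event) {
  checkSurv(time, event)
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1L))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1L))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                    survival = surv)
  class(out) <- c("kmEstimate", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier fit at arbitrary times
#' @param km a [kmEstimate()] result.
#' @param t times at which to evaluate `S(t)` (right-continuous step).
#' @return numeric vector of survival probabilities.
#' @export
kmSurvivalAt <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (length(i) == 0L) 1 else km$survival[max(i)]
  }, numeric(1L))
}

#' Two-group log-rank test
#'
#' Standard log-rank with hypergeometric variance accumulated over distinct
#' event times; the statistic is referred to a chi-square with 1 df.
#'
#' @param time,event pooled survival data.
#' @param group two-level grouping vector (factor/character/logical).
#' @return list with `chisq`, `p`, `observed` and `expected` event counts
#'   per group, and the group `levels`.
#' @export
logrankTest <- function(time, event, group) {
  checkSurv(time, event)
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("log-rank requires exactly two groups")
  if (any(table(g) == 0L)) stop("both groups must be non-empty")
  if (sum(event) == 0L) stop("no events")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  is1 <- (g == levels(g)[1L])[ord]
  n <- length(time)
  ut <- unique(time)
  first <- match(ut, time)
  last <- c(first[-1L] - 1L, n)
  sumsByUnique <- function(v) {
    cs <- cumsum(v)
    cs[last] - c(0, cs[last[-length(last)]])
  }
  d <- sumsByUnique(event)
  d1 <- sumsByUnique(event * is1)
  n_risk <- n - first + 1
  n1_risk <- rev(cumsum(rev(as.numeric(is1))))[first]
  has <- d > 0
  d <- d[has]; d1 <- d1[has]; nr <- n_risk[has]; n1r <- n1_risk[has]
  o1 <- sum(d1)
  e1 <- sum(d * n1r / nr)
  vterms <- d * (n1r / nr) * (1 - n1r / nr) * (nr - d) / pmax(nr - 1, 1)
  v <- sum(vterms[nr > 1])
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  obs <- c(o1, sum(event) - o1)
  exp_ <- c(e1, sum(event) - e1)
  names(obs) <- names(exp_) <- levels(g)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       observed = obs, expected = exp_, levels = levels(g))
}

# Breslow partial log-likelihood, score vector and information matrix at
# beta, for data pre-sorted by increasing time. Ties grouped by event time.
# All risk-set sums S0, S1, S2 are reverse cumulative sums over the sorted
# data, evaluated at the first index of each unique time, so one call is
# O(n p^2) rather than O(n^2).
coxLikParts <- function(beta, time, event, X) {
  eta <- drop(X %*% beta)
  eta <- pmin(eta, 500)                     # overflow guard
  w <- exp(eta)
  p <- ncol(X)
  ut <- unique(time)                        # sorted, as time is sorted
  first <- match(ut, time)
  last <- c(first[-1L] - 1L, length(time))
  revcs <- function(v) rev(cumsum(rev(v)))
  sumsByUnique <- function(v) {             # per-unique-time sums, O(n)
    cs <- cumsum(v)
    cs[last] - c(0, cs[last[-length(last)]])
  }
  S0 <- revcs(w)[first]
  S1 <- matrix(0, length(ut), p)
  for (j in seq_len(p)) S1[, j] <- revcs(X[, j] * w)[first]
  d <- sumsByUnique(event)                  # events per unique time
  has <- d > 0
  loglik <- sum(eta * event) - sum(d[has] * log(S0[has]))
  xbar <- S1 / S0
  U <- colSums(X * event) -
    colSums(d[has] * xbar[has, , drop = FALSE])
  I <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in j:p) {
    s2jk <- revcs(X[, j] * X[, k] * w)[first]
    val <- sum(d[has] * (s2jk[has] / S0[has] - xbar[has, j] * xbar[has, k]))
    I[j, k] <- val; I[k, j] <- val
  }
  list(loglik = loglik, U = U, I = I)
}

#' Cox proportional-hazards fit (Breslow ties, Newton-Raphson)
#'
#' Maximizes the Cox partial likelihood with Breslow tie handling.
#' Convergence is declared when `max |score| < 1e-8` or the relative change
#' in partial log-likelihood falls below 1e-10, within 50 iterations;
#' coefficients are capped at |beta| = 20 and a fit hitting the cap or the
#' iteration limit is flagged `converged = FALSE` rather than silently
#' returned. Standard errors come from the inverse observed information;
#' p-values are two-sided Wald.
#'
#' @param time,event survival data.
#' @param X covariate matrix (or vector for a single covariate).
#' @return list of class `"coxFit"`: `coef` (log-HR), `se`, `z`, `p`,
#'   `loglik`, `loglik_null`, `score_chisq` (global score test at beta = 0,
#'   which for a single binary covariate equals the log-rank chi-square),
#'   `iter`, `converged`.
#' @export
coxFit <- function(time, event, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L,
                                   dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  checkSurv(time, event)
  stopifnot(nrow(X) == length(time))
  if (length(time) <= ncol(X)) stop("more covariates than samples")
  if (any(apply(X, 2L, function(v) length(unique(v))) == 1L))
    stop("degenerate design: constant covariate")
  if (sum(event) == 0L) stop("no events")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  Xc <- sweep(X, 2L, colMeans(X))           # center for numerical stability
  p <- ncol(X)
  beta <- numeric(p)
  parts <- coxLikParts(beta, time, event, Xc)
  loglik_null <- parts$loglik
  I0inv <- tryCatch(solve(parts$I), error = function(e)
    stop("degenerate design: singular information matrix"))
  score_chisq <- drop(t(parts$U) %*% I0inv %*% parts$U)
  converged <- FALSE; iter <- 0L; ll_old <- parts$loglik
  repeat {
    iter <- iter + 1L
    step <- tryCatch(solve(parts$I, parts$U), error = function(e)
      stop("degenerate design: singular information matrix"))
    beta_new <- beta + step
    beta_new <- pmin(pmax(beta_new, -20), 20)
    parts_new <- coxLikParts(beta_new, time, event, Xc)
    # step-halve only if the likelihood worsened (rare, near the cap)
    h <- 0L
    while (parts_new$loglik < ll_old - 1e-12 && h < 10L) {
      h <- h + 1L
      beta_new <- (beta + beta_new) / 2
      parts_new <- coxLikParts(beta_new, time, event, Xc)
    }
    beta <- beta_new; parts <- parts_new
    if (max(abs(parts$U)) < 1e-8 ||
        abs(parts$loglik - ll_old) < 1e-10 * (abs(ll_old) + 1e-10)) {
      converged <- max(abs(beta)) < 20
      break
    }
    ll_old <- parts$loglik
    if (iter >= 50L) break
  }
  V <- tryCatch(solve(parts$I), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(V), 0))
  z <- beta / se
  out <- list(coef = stats::setNames(beta, colnames(X)),
              se = stats::setNames(se, colnames(X)),
              z = z, p = 2 * stats::pnorm(-abs(z)),
              loglik = parts$loglik, loglik_null = loglik_null,
              score_chisq = score_chisq, iter = iter, converged = converged)
  class(out) <- "coxFit"
  out
}

#' @export
print.coxFit <- function(x, ...) {
  cat(sprintf("Cox fit (Breslow ties), %sconverged in %d iteration(s)\n",
              if (x$converged) "" else "NOT ", x$iter))
  print(data.frame(coef = x$coef, `exp(coef)` = exp(x$coef), se = x$se,
                   z = x$z, p = x$p, check.names = FALSE))
  invisible(x)
}

# Screening hot path: Newton-Raphson for a single binary 0/1 covariate,
# with the per-cohort sort/tie structure precomputed once and shared across
# genes. For x in {0,1}, exp(beta*x) splits the Breslow risk-set sum into
# S0 = R0 + exp(beta)*R1 with beta-independent R0/R1, so one iteration is
# O(#event times). Same likelihood, convergence rules and SE as coxFit.
prepCoxBinary <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time); first <- match(ut, time)
  last <- c(first[-1L] - 1L, length(time))
  cs <- cumsum(event)
  d <- cs[last] - c(0, cs[last[-length(last)]])
  has <- d > 0
  list(ord = ord, event = event, first = first[has], d = d[has],
       n = length(time))
}

coxBinaryFast <- function(prep, x) {
  x <- x[prep$ord]
  r1 <- rev(cumsum(rev(x)))[prep$first]      # high-group members at risk
  nrisk <- prep$n - prep$first + 1
  r0 <- nrisk - r1
  ex <- sum(x * prep$event)
  d <- prep$d
  parts <- function(b) {
    eb <- exp(b)
    s0 <- r0 + eb * r1
    pt <- eb * r1 / s0
    list(ll = b * ex - sum(d * log(s0)), U = ex - sum(d * pt),
         I = sum(d * pt * (1 - pt)))
  }
  beta <- 0
  pa <- parts(0)
  ll_old <- pa$ll
  converged <- FALSE; iter <- 0L
  repeat {
    iter <- iter + 1L
    if (!is.finite(pa$I) || pa$I <= 0) break
    bn <- beta + pa$U / pa$I
    bn <- min(max(bn, -20), 20)
    pn <- parts(bn)
    h <- 0L
    while (pn$ll < ll_old - 1e-12 && h < 10L) {
      h <- h + 1L; bn <- (beta + bn) / 2; pn <- parts(bn)
    }
    beta <- bn; pa <- pn
    if (abs(pa$U) < 1e-8 ||
        abs(pa$ll - ll_old) < 1e-10 * (abs(ll_old) + 1e-10)) {
      converged <- abs(beta) < 20
      break
    }
    ll_old <- pa$ll
    if (iter >= 50L) break
  }
  se <- if (is.finite(pa$I) && pa$I > 0) 1 / sqrt(pa$I) else NA_real_
  z <- beta / se
  list(coef = beta, se = se, p = 2 * stats::pnorm(-abs(z)),
       converged = converged && is.finite(se))
}

# KM of the censoring distribution evaluated as G(t) = P(C > t);
# 'minus' evaluates the left limit G(t-)
censoringSurvival <- function(time, event, t, minus = FALSE) {
  km <- kmEstimate(time, 1 - event)
  vapply(t, function(tt) {
    i <- if (minus) which(km$time < tt) else which(km$time <= tt)
    if (length(i) == 0L) 1 else km$survival[max(i)]
  }, numeric(1L))
}

#' Time-dependent ROC AUC (IPCW cumulative/dynamic)
#'
#' Discrimination of a risk score for the binary status "event by the
#' horizon", under right censoring. Cases are subjects with an observed
#' event at or before the horizon, controls are subjects still under
#' observation past it; each pair is weighted by inverse probabilities of
#' censoring from the Kaplan-Meier estimate of the censoring distribution
#' (cases at the left limit of their event time, controls at the horizon).
#' Ties in the score receive half credit. With no censoring before the
#' horizon this reduces to the plain Mann-Whitney AUC.
#'
#' @param scores risk scores (higher = higher risk).
#' @param time,event survival data.
#' @param horizon evaluation time (months), within the observed time range.
#' @return AUC in `[0, 1]`.
#' @export
tdRocAuc <- function(scores, time, event, horizon) {
  checkSurv(time, event)
  stopifnot(length(scores) == length(time))
  if (horizon <= 0 || horizon > max(time))
    stop("horizon outside the observed time range")
  case <- time <= horizon & event == 1
  ctrl <- time > horizon
  if (!any(case)) stop("no events before the horizon")
  if (!any(ctrl)) stop("no survivors past the horizon")
  wc <- 1 / censoringSurvival(time, event, time[case], minus = TRUE)
  wk <- rep(1 / censoringSurvival(time, event, horizon), sum(ctrl))
  sc <- scores[case]; sk <- scores[ctrl]
  cmp <- outer(sc, sk, function(a, b) (a > b) + 0.5 * (a == b))
  ww <- outer(wc, wk)
  sum(ww * cmp) / sum(ww)
}
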