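#' Split marker values at the cohort median
#'
#' Patients at or above the median are labelled "high", below it "low"
#' (ties at the median go to "high"). Errors if either group is empty
#' (e.g. all values identical).
#'
#' @param values Numeric vector (>= 2 finite values).
#' @return Character vector of labels "low"/"high".
#' @examples
#' median_split(c(1, 2, 2, 9))
#' @export
median_split <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) stop("need at least 2 finite values")
  med <- stats::median(values, na.rm = TRUE)
  lab <- ifelse(values >= med, "high", "low")
  lab[!is.finite(values)] <- NA_character_
  if (!any(lab == "low", na.rm = TRUE) || !any(lab == "high", na.rm = TRUE))
    stop("median split produces an empty group (degenerate values)")
  lab
}

# normalize (records | time,event) arguments into a list(time, event)
surv_args <- function(records, event = NULL) {
  if (is.data.frame(records)) {
    time <- records$time
    event <- records$event
  } else {
    time <- records
    if (is.null(event)) stop("event indicator required")
  }
  if (any(time < 0)) stop("negative survival times")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  list(time = as.numeric(time), event = as.integer(event))
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the survivor function S(t) = prod_(t_k <= t) (1 - d_k/n_k) over
#' distinct event times, Greenwood standard errors, log-log 95% confidence
#' bands, and the median survival time (smallest t with S(t) <= 0.5;
#' undefined when S never reaches 0.5) with a Brookmeyer-Crowley-style
#' confidence interval from the band crossings.
#'
#' @param records data.frame with columns `time`, `event`, or a numeric
#'   time vector (then `event` as second argument).
#' @param event Optional event vector when `records` is a time vector.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `km_estimate`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `se` (of S), `lower`, `upper`, `median`,
#'   `median_ci`, `n`, `events`.
#' @export
km_estimate <- function(records, event = NULL, conf_level = 0.95) {
  a <- surv_args(records, event = event)
  time <- a$time; ev <- a$event
  ord <- order(time)
  time <- time[ord]; ev <- ev[ord]
  n <- length(time)
  tk <- sort(unique(time[ev == 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n_risk <- n_event <- n_cens <- integer(length(tk))
  surv <- se <- lower <- upper <- numeric(length(tk))
  s <- 1
  gw <- 0   # running Greenwood sum: sum d / (n (n - d))
  for (k in seq_along(tk)) {
    t_ <- tk[k]
    n_risk[k] <- sum(time >= t_)
    n_event[k] <- sum(time == t_ & ev == 1)
    n_cens[k] <- sum(time == t_ & ev == 0)
    s <- s * (1 - n_event[k] / n_risk[k])
    if (n_risk[k] > n_event[k])
      gw <- gw + n_event[k] / (n_risk[k] * (n_risk[k] - n_event[k]))
    else gw <- Inf
    surv[k] <- s
    se[k] <- if (is.finite(gw)) s * sqrt(gw) else 0
    if (s > 0 && s < 1 && is.finite(gw)) {
      # log-log transform CI: exp(-exp(log(-log S) -+ z * se_ll))
      se_ll <- sqrt(gw) / abs(log(s))
      lower[k] <- exp(-exp(log(-log(s)) + z * se_ll))
      upper[k] <- exp(-exp(log(-log(s)) - z * se_ll))
    } else {
      lower[k] <- upper[k] <- s
    }
  }
  med <- if (any(surv <= 0.5)) tk[which(surv <= 0.5)[1]] else NA_real_
  ci_lo <- if (any(lower <= 0.5)) tk[which(lower <= 0.5)[1]] else NA_real_
  ci_hi <- if (any(upper <= 0.5)) tk[which(upper <= 0.5)[1]] else NA_real_
  structure(list(time = tk, n_risk = n_risk, n_event = n_event,
                 n_censor = n_cens, surv = surv, se = se,
                 lower = lower, upper = upper,
                 median = med, median_ci = c(ci_lo, ci_hi),
                 n = n, events = sum(ev), conf_level = conf_level),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, ", events =", x$events, "\n")
  if (is.na(x$median)) {
    cat("  median survival not reached\n")
  } else {
    cat(sprintf("  median survival %.3g [%s, %s] (%.0f%% CI)\n",
                x$median,
                ifelse(is.na(x$median_ci[1]), "NA",
                       sprintf("%.3g", x$median_ci[1])),
                ifelse(is.na(x$median_ci[2]), "NA",
                       sprintf("%.3g", x$median_ci[2])),
                100 * x$conf_level))
  }
  invisible(x)
}

#' @export
plot.km_estimate <- function(x, conf = TRUE, xlab = "Time (months)",
                             ylab = "Survival probability", ...) {
  t_ <- c(0, x$time); s_ <- c(1, x$surv)
  graphics::plot(t_, s_, type = "s", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  if (conf && length(x$time)) {
    graphics::lines(c(0, x$time), c(1, x$lower), type = "s", lty = 3)
    graphics::lines(c(0, x$time), c(1, x$upper), type = "s", lty = 3)
  }
  invisible(x)
}

#' Log-rank test for k groups
#'
#' Standard log-rank chi-square on df = k - 1, built from the per-event-time
#' hypergeometric observed-minus-expected sums and their covariance matrix.
#'
#' @param records data.frame with `time`, `event` columns (or time vector).
#' @param groups Group labels, one per record (>= 2 groups, each nonempty).
#' @param event Optional event vector when `records` is a time vector.
#' @return List of class `logrank_test`: `chisq`, `df`, `p_value`,
#'   `observed`, `expected`, `n` (per group).
#' @export
logrank_test <- function(records, groups, event = NULL) {
  a <- surv_args(records, event = event)
  time <- a$time; ev <- a$event
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  stopifnot(length(g) == length(time))
  k <- nlevels(g)
  tk <- sort(unique(time[ev == 1]))
  O <- E <- stats::setNames(numeric(k), levels(g))
  V <- matrix(0, k, k, dimnames = list(levels(g), levels(g)))
  for (t_ in tk) {
    at_risk <- time >= t_
    n_j <- sum(at_risk)
    d_j <- sum(time == t_ & ev == 1)
    if (n_j == 0 || d_j == 0) next
    n_gj <- tabulate(g[at_risk], nbins = k)
    d_gj <- tabulate(g[time == t_ & ev == 1], nbins = k)
    e_gj <- d_j * n_gj / n_j
    O <- O + d_gj
    E <- E + e_gj
    if (n_j > 1) {
      fac <- d_j * (n_j - d_j) / (n_j - 1)
      p <- n_gj / n_j
      V <- V + fac * (diag(p, k) - tcrossprod(p))
    }
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chisq <- tryCatch(drop(t(u) %*% solve(Vk, u)),
                    error = function(e) {
                      # singular covariance (e.g. empty risk overlap):
                      # use the Moore-Penrose inverse
                      sv <- svd(Vk)
                      pos <- sv$d > max(sv$d) * 1e-12
                      drop(t(u) %*% sv$v[, pos, drop = FALSE] %*%
                             ((t(sv$u[, pos, drop = FALSE]) %*% u) / sv$d[pos]))
                    })
  if (!is.finite(chisq) || chisq < 0) chisq <- 0
  df <- k - 1L
  structure(list(chisq = chisq, df = df,
                 p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
                 observed = O, expected = E, n = table(g)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  tab <- data.frame(n = as.integer(x$n), observed = x$observed,
                    expected = x$expected)
  print(tab)
  invisible(x)
}

# Cox partial likelihood, gradient and information at beta.
# Efron or Breslow tie corrections. X: n x p, sorted arbitrary.
cox_loglik <- function(beta, time, event, X, ties = "efron") {
  n <- length(time); p <- ncol(X)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)                 # guard exp overflow
  w <- exp(eta)
  # reverse cumulative risk-set sums over sorted times
  wx <- X * w
  S0 <- rev(cumsum(rev(w)))
  S1 <- apply(wx, 2, function(cl) rev(cumsum(rev(cl))))
  S1 <- matrix(S1, ncol = p)
  # S2 as list of p x p lower-triangular sums: build cumulative outer sums
  xx <- array(0, c(n, p, p))
  for (a in seq_len(p)) for (b in seq_len(p))
    xx[, a, b] <- w * X[, a] * X[, b]
  S2 <- array(0, c(n, p, p))
  for (a in seq_len(p)) for (b in seq_len(p))
    S2[, a, b] <- rev(cumsum(rev(xx[, a, b])))
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  ut <- unique(time[event == 1])
  first_idx <- match(time, time)        # first row with each time value
  for (t_ in ut) {
    i0 <- which(time == t_)[1]          # risk set = rows i0..n
    D <- which(time == t_ & event == 1)
    d <- length(D)
    s0 <- S0[i0]
    s1 <- S1[i0, ]
    s2 <- S2[i0, , ]
    if (p == 1) s2 <- matrix(s2, 1, 1)
    sum_eta <- sum(eta[D])
    sum_x <- colSums(X[D, , drop = FALSE])
    if (ties == "breslow" || d == 1) {
      ll <- ll + sum_eta - d * log(s0)
      mu <- s1 / s0
      U <- U + sum_x - d * mu
      I <- I + d * (s2 / s0 - tcrossprod(mu))
    } else {
      # Efron: fractional removal of the tied deaths' own risk mass
      w_D <- sum(w[D])
      x_D <- colSums(X[D, , drop = FALSE] * w[D])
      s2_D <- matrix(0, p, p)
      for (i in D) s2_D <- s2_D + w[i] * tcrossprod(X[i, ])
      ll <- ll + sum_eta
      for (l in 0:(d - 1)) {
        f <- l / d
        s0l <- s0 - f * w_D
        s1l <- s1 - f * x_D
        s2l <- s2 - f * s2_D
        ll <- ll - log(s0l)
        mu <- s1l / s0l
        U <- U + sum_x / d - mu
        I <- I + s2l / s0l - tcrossprod(mu)
      }
    }
  }
  list(loglik = ll, gradient = U, information = I)
}

#' Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by default,
#' Breslow optional) to a gradient max-norm below `tol`, with step-halving
#' on decreases. Standard errors come from the observed information; Wald z
#' and two-sided p-values per covariate.
#'
#' @param records data.frame with columns `time`, `event` and the
#'   covariates.
#' @param covariate_names Character vector of numeric/binary covariate
#'   columns (factor columns are not auto-encoded; pre-code them).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton-Raphson controls (defaults 50, 1e-8; the
#'   gradient criterion is scaled by the magnitude of the log likelihood).
#' @return List of class `cox_fit`: `coefficients` (data.frame term, beta,
#'   se, z, p, hr), `beta`, `var` (covariance), `loglik` (c(null, final)),
#'   `iter`, `ties`, `n`, `nevent`.
#' @export
cox_fit <- function(records, covariate_names, ties = c("efron", "breslow"),
                    max_iter = 50L, tol = 1e-8) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(records))
  a <- surv_args(records)
  missing_cov <- setdiff(covariate_names, names(records))
  if (length(missing_cov))
    stop("covariates not in records: ", paste(missing_cov, collapse = ", "))
  X <- as.matrix(records[, covariate_names, drop = FALSE])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("covariates must be finite")
  if (sum(a$event) < 1L) stop("need at least one event")
  const <- apply(X, 2, function(cl) stats::var(cl) == 0)
  if (any(const))
    stop("constant covariate(s): ",
         paste(covariate_names[const], collapse = ", "))
  # center covariates for numerical stability (does not change beta)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  p <- ncol(Xc)
  beta <- numeric(p)
  fit0 <- cox_loglik(beta, a$time, a$event, Xc, ties)
  ll0 <- fit0$loglik
  ll <- ll0; U <- fit0$gradient; I <- fit0$information
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(I, U), error = function(e)
      stop("singular information matrix (collinear covariates?)"))
    new_beta <- beta + step
    fit <- cox_loglik(new_beta, a$time, a$event, Xc, ties)
    halvings <- 0L
    while (fit$loglik < ll && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      fit <- cox_loglik(new_beta, a$time, a$event, Xc, ties)
      halvings <- halvings + 1L
    }
    beta <- new_beta; ll <- fit$loglik; U <- fit$gradient
    I <- fit$information
    if (max(abs(U)) < tol * max(1, abs(ll))) { converged <- TRUE; break }
  }
  if (converged && any(abs(beta) > 15))
    stop("monotone partial likelihood (separation): coefficient for ",
         paste(covariate_names[abs(beta) > 15], collapse = ", "),
         " diverges")
  if (!converged)
    stop("Cox Newton-Raphson did not converge in ", max_iter,
         " iterations (max |gradient| = ", signif(max(abs(U)), 3),
         ", max |beta| = ", signif(max(abs(beta)), 3),
         "); possible monotone partial likelihood (separation)")
  V <- solve(I)
  se <- sqrt(diag(V))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(term = covariate_names, beta = beta, se = se,
                      z = z, p = pv, hr = exp(beta),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = coefs,
                 beta = stats::setNames(beta, covariate_names),
                 var = V, loglik = c(null = ll0, final = ll),
                 iter = iter, ties = ties,
                 n = nrow(records), nevent = sum(a$event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$nevent, "\n", sep = "")
  tab <- x$coefficients
  tab[, -1] <- lapply(tab[, -1], signif, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("log partial likelihood: %.4f (null %.4f)\n",
              x$loglik["final"], x$loglik["null"]))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$beta

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' @export
summary.cox_fit <- function(object, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- object$coefficients
  tab$hr_lower <- exp(tab$beta - z * tab$se)
  tab$hr_upper <- exp(tab$beta + z * tab$se)
  tab
}

#' Cox score test at beta = 0
#'
#' The score chi-square U' I^-1 U evaluated at the null; with one binary
#' covariate and Breslow ties this reproduces the log-rank statistic.
#'
#' @inheritParams cox_fit
#' @return List: `chisq`, `df`, `p_value`.
#' @export
cox_score_test <- function(records, covariate_names,
                           ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  a <- surv_args(records)
  X <- as.matrix(records[, covariate_names, drop = FALSE])
  storage.mode(X) <- "double"
  Xc <- sweep(X, 2, colMeans(X))
  f <- cox_loglik(numeric(ncol(Xc)), a$time, a$event, Xc, ties)
  chisq <- drop(t(f$gradient) %*% solve(f$information, f$gradient))
  df <- ncol(Xc)
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Backward elimination on Wald p-values
#'
#' Repeatedly refits the Cox model, dropping the covariate with the largest
#' Wald p-value above `alpha_out`, until every remaining covariate is
#' significant at `alpha_out` (or no covariate remains).
#'
#' @inheritParams cox_fit
#' @param alpha_out Stay-in threshold (default 0.05); `alpha_out = 1`
#'   never eliminates.
#' @return List of class `backward_cox`: `path` (list of `cox_fit`),
#'   `removed` (character, in elimination order), `final` (`cox_fit` or
#'   `NULL` when everything was eliminated).
#' @export
backward_eliminate <- function(records, covariate_names, alpha_out = 0.05,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  remaining <- covariate_names
  path <- list()
  removed <- character(0)
  repeat {
    if (!length(remaining)) break
    fit <- cox_fit(records, remaining, ties = ties)
    path[[length(path) + 1L]] <- fit
    worst <- which.max(fit$coefficients$p)
    if (fit$coefficients$p[worst] <= alpha_out) break
    removed <- c(removed, remaining[worst])
    remaining <- remaining[-worst]
  }
  structure(list(path = path, removed = removed,
                 final = if (length(remaining)) path[[length(path)]] else NULL,
                 alpha_out = alpha_out),
            class = "backward_cox")
}

#' @export
print.backward_cox <- function(x, ...) {
  cat("Backward Wald elimination (alpha_out =", x$alpha_out, ")\n")
  if (length(x$removed))
    cat("  removed:", paste(x$removed, collapse = " -> "), "\n")
  else cat("  no covariate removed\n")
  if (!is.null(x$final)) print(x$final) else cat("  all covariates eliminated\n")
  invisible(x)
}

#' Median-split survival comparison for one marker
#'
#' Convenience wrapper for the prognostic workflow: split a cohort at the
#' median of a marker column, estimate per-group Kaplan-Meier curves, and
#' compare them by log-rank.
#'
#' @param records Cohort data.frame (`time`, `event`, marker column).
#' @param marker Name of the numeric marker column.
#' @return List of class `km_comparison`: `groups`, `km` (named list of
#'   `km_estimate`), `logrank`.
#' @export
compare_survival_by_marker <- function(records, marker) {
  stopifnot(marker %in% names(records))
  grp <- median_split(records[[marker]])
  km <- lapply(split(records, grp), km_estimate)
  structure(list(marker = marker, groups = grp, km = km,
                 logrank = logrank_test(records, grp)),
            class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  cat("Median-split survival comparison on", x$marker, "\n")
  for (g in names(x$km)) {
    cat(" ", g, ": ")
    print(x$km[[g]])
  }
  print(x$logrank)
  invisible(x)
}
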