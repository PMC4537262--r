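r_squared <- function(y, fitted) {
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  1 - ss_res / ss_tot
}

#' Fit a power law y = k * x^alpha
#'
#' Nonlinear least squares on the original scale, initialized from the
#' log-log linear regression; `r2` is the coefficient of determination on the
#' original scale. This is the Heaps-law workhorse behind pan-genome size and
#' new-gene curves (`n = k * N^alpha`, alpha < 0 decaying).
#'
#' @param x,y numeric vectors (same length, >= 3 points, x >= 1, y > 0).
#' @return a `power_fit`: `k`, `alpha`, `r2`, `n_points`, `converged`.
#' @export
fit_power <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (any(x < 1)) stop("x must be >= 1")
  if (any(y <= 0)) stop("all y must be > 0 (log-scale initialization)")
  init <- stats::lm(log(y) ~ log(x))
  start <- list(k = exp(stats::coef(init)[[1]]), alpha = stats::coef(init)[[2]])
  fit <- tryCatch(
    stats::nls(y ~ k * x^alpha, start = start,
               control = stats::nls.control(maxiter = 200, scaleOffset = 1,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    cf <- unlist(start)
    conv <- FALSE
  } else {
    cf <- stats::coef(fit)
    conv <- TRUE
  }
  structure(list(k = unname(cf[["k"]]), alpha = unname(cf[["alpha"]]),
                 r2 = r_squared(y, cf[["k"]] * x^cf[["alpha"]]),
                 n_points = length(x), converged = conv),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("power_fit: y = %.4g * x^%.4g  (R2 = %.6g, n = %d%s)\n",
              x$k, x$alpha, x$r2, x$n_points,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fit a power law plus linear trend y = K * x^a + b * x + c
#'
#' The core-genome model: a decaying power term on top of a linear drift.
#' The 4-parameter surface is multimodal, so a multi-start strategy is used:
#' for each initial exponent a0 in `starts`, (K, b, c) are initialized by
#' ordinary least squares with the power term fixed, then all four parameters
#' are refined by nonlinear least squares; the best SSE wins.
#'
#' @param x,y numeric vectors (>= 5 points).
#' @param starts initial exponents tried (default -0.5, -1, -2).
#' @return a `core_fit`: `K`, `a`, `b`, `c`, `r2`, `n_points`, `converged`.
#' @export
fit_core <- function(x, y, starts = c(-0.5, -1, -2)) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 5) stop("need at least 5 points")
  best <- NULL
  for (a0 in starts) {
    lin <- stats::lm(y ~ I(x^a0) + x)
    st <- list(K = stats::coef(lin)[[2]], a = a0,
               b = stats::coef(lin)[[3]], c = stats::coef(lin)[[1]])
    fit <- tryCatch(
      stats::nls(y ~ K * x^a + b * x + c, start = st,
                 control = stats::nls.control(maxiter = 500, scaleOffset = 1,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(cf = stats::coef(fit), sse = sse)
  }
  if (is.null(best)) {
    # fall back to the best fixed-exponent linearization, flagged unconverged
    sses <- sapply(starts, function(a0) sum(stats::resid(stats::lm(y ~ I(x^a0) + x))^2))
    a0 <- starts[which.min(sses)]
    lin <- stats::lm(y ~ I(x^a0) + x)
    cf <- c(K = stats::coef(lin)[[2]], a = a0, b = stats::coef(lin)[[3]],
            c = stats::coef(lin)[[1]])
    conv <- FALSE
  } else {
    cf <- best$cf
    conv <- TRUE
  }
  structure(list(K = unname(cf[["K"]]), a = unname(cf[["a"]]),
                 b = unname(cf[["b"]]), c = unname(cf[["c"]]),
                 r2 = r_squared(y, cf[["K"]] * x^cf[["a"]] + cf[["b"]] * x + cf[["c"]]),
                 n_points = length(x), converged = conv),
            class = "core_fit")
}

#' @export
print.core_fit <- function(x, ...) {
  cat(sprintf("core_fit: y = %.4g * x^%.4g %+.4g x %+.4g  (R2 = %.6g%s)\n",
              x$K, x$a, x$b, x$c, x$r2,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Classify pan-genome openness from a new-gene power fit
#'
#' An exponent strictly between -1 and 0 marks an open pan-genome (new genes
#' keep arriving, their number decaying slower than 1/N); alpha <= -1 marks a
#' closed one (the boundary itself is assigned to "closed" since openness is
#' strictly inside the interval). A non-negative exponent does not decay and
#' is flagged.
#'
#' @param fit a [fit_power()] result (converged).
#' @return `"open"`, `"closed"`, or `"non-decaying"`.
#' @export
classify_openness <- function(fit) {
  stopifnot(inherits(fit, "power_fit"))
  a <- fit$alpha
  if (a >= 0) return("non-decaying")
  if (a > -1) "open" else "closed"
}

#' Strains needed to slow pan-genome growth below a threshold
#'
#' Smallest integer N with `k * N^alpha <= threshold` for a decaying fit,
#' i.e. the number of added strains after which fewer than `threshold` new
#' ortholog groups are expected per added strain.
#'
#' @param fit a [fit_power()] result with `alpha < 0` and `k > 0`, or a
#'   numeric `k` when `alpha` is given explicitly.
#' @param threshold new groups per strain (> 0).
#' @param alpha optional explicit exponent when `fit` is a bare amplitude.
#' @return integer N.
#' @export
strains_to_threshold <- function(fit, threshold = 1, alpha = NULL) {
  if (inherits(fit, "power_fit")) {
    k <- fit$k
    a <- fit$alpha
  } else {
    k <- fit
    a <- alpha
  }
  if (is.null(a)) stop("alpha required")
  if (threshold <= 0) stop("threshold must be > 0")
  if (a >= 0) stop("non-decaying fit (alpha >= 0) never reaches the threshold")
  if (k <= threshold) return(1L)
  N <- ceiling((k / threshold)^(-1 / a))
  if (N < 2^52) {
    # guard the ceiling against floating-point slop on either side
    while (N > 1 && k * (N - 1)^a <= threshold) N <- N - 1
    while (k * N^a > threshold) N <- N + 1
  }
  if (N <= .Machine$integer.max) as.integer(N) else N
}

#' Delete-half jackknife distribution of the openness exponent
#'
#' Repeatedly keeps ceiling(n/2) strains chosen uniformly without
#' replacement, recomputes the mean new-gene curve by permutation
#' accumulation within the subsample, refits the power law, and collects the
#' exponents. Subsamples whose mean new-gene curve is degenerate (a zero mean
#' at some k, so the log-scale fit is impossible — e.g. identical strains)
#' are skipped and counted.
#'
#' @param m an [ortholog_matrix()] with >= 4 strains.
#' @param n_subsamples number of delete-half subsamples (default 2000).
#' @param n_perm_per_subsample permutations per subsample (default 1000).
#' @param seed master seed; per-subsample seeds are drawn from one seeded
#'   stream so runs are reproducible.
#' @param drop_first exclude the k = 1 point from each fit (default FALSE).
#' @return a `jackknife_alpha` object: `alpha` (vector), `n_skipped`, and
#'   `summary` (min/mean/max).
#' @export
jackknife_alpha <- function(m, n_subsamples = 2000L,
                            n_perm_per_subsample = 1000L, seed = 1L,
                            drop_first = FALSE) {
  stopifnot(inherits(m, "ortholog_matrix"))
  n <- nrow(m$occurrence)
  if (n < 4L) stop("need at least 4 strains")
  keep_n <- ceiling(n / 2)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_subsamples)
  alphas <- rep(NA_real_, n_subsamples)
  for (i in seq_len(n_subsamples)) {
    set.seed(sub_seeds[i])
    sel <- sample(m$strains, keep_n)
    sub <- subset_matrix(m, strains = sel)
    cur <- accumulate(sub, n_perm = n_perm_per_subsample,
                      seed = sub_seeds[i])
    ybar <- colMeans(cur$samples$new)
    x <- seq_len(keep_n)
    if (drop_first) {
      x <- x[-1]
      ybar <- ybar[-1]
    }
    if (any(ybar <= 0) || length(x) < 3) next
    alphas[i] <- fit_power(x, ybar)$alpha
  }
  ok <- !is.na(alphas)
  structure(list(alpha = alphas[ok], n_skipped = sum(!ok),
                 summary = c(min = suppressWarnings(min(alphas[ok])),
                             mean = mean(alphas[ok]),
                             max = suppressWarnings(max(alphas[ok])))),
            class = "jackknife_alpha")
}

#' @export
print.jackknife_alpha <- function(x, ...) {
  cat(sprintf("jackknife_alpha: %d fits (%d skipped); alpha mean %.3f, range [%.3f, %.3f]\n",
              length(x$alpha), x$n_skipped, x$summary[["mean"]],
              x$summary[["min"]], x$summary[["max"]]))
  invisible(x)
}
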