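# per-order curves for one inclusion order: positions of first presence /
# first absence give new/pan/core in O(n * G)
perm_curves <- function(P, ord) {
  n <- nrow(P)
  G <- ncol(P)
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  fp <- rep(Inf, G)   # first inclusion step at which the group is present
  fa <- rep(Inf, G)   # first step at which a strain lacking it is included
  for (s in seq_len(n)) {
    pres <- P[s, ] > 0L
    if (any(pres)) fp[pres] <- pmin(fp[pres], pos[s])
    if (!all(pres)) fa[!pres] <- pmin(fa[!pres], pos[s])
  }
  newk <- tabulate(fp[is.finite(fp)], nbins = n)
  lost <- tabulate(fa[is.finite(fa)], nbins = n)
  list(pan = cumsum(newk), core = G - cumsum(lost), new = newk)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    blk <- cbind(i, matrix(rest[sub], nrow(sub)))
    out[row + seq_len(nrow(sub)), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

#' Permutation accumulation curves for pan-, core- and new-gene counts
#'
#' For each random order of sequential strain inclusion, `pan(k)` is the
#' number of distinct groups seen in the first k strains, `core(k)` the number
#' present in all of them, and `new(k) = pan(k) - pan(k - 1)`. With
#' `n <= exact_max` strains every one of the n! orders is enumerated instead
#' of sampling (and `n_perm` is ignored).
#'
#' @param m an [ortholog_matrix()].
#' @param n_perm number of random permutations (>= 1) in sampled mode.
#' @param seed integer seed for the permutation stream.
#' @param exact_max largest n for which exact enumeration replaces sampling
#'   (default 8).
#' @return an `accumulation_curves` object: `n`, `n_perm`, `mode`, `seed`,
#'   and `samples`, a list of three `n_perm x n` matrices `pan`, `core`,
#'   `new` (one row per inclusion order).
#' @export
accumulate <- function(m, n_perm = 10000L, seed = 1L, exact_max = 8L) {
  stopifnot(inherits(m, "ortholog_matrix"))
  n <- nrow(m$occurrence)
  if (n < 1L) stop("matrix has no strains")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  P <- presence(m)
  if (n <= exact_max) {
    orders <- all_permutations(n)
    mode <- "exact"
  } else {
    set.seed(seed)
    orders <- t(replicate(n_perm, sample.int(n)))
    mode <- "sampled"
  }
  res <- lapply(seq_len(nrow(orders)),
                function(i) perm_curves(P, orders[i, ]))
  samples <- list(
    pan = do.call(rbind, lapply(res, `[[`, "pan")),
    core = do.call(rbind, lapply(res, `[[`, "core")),
    new = do.call(rbind, lapply(res, `[[`, "new")))
  structure(list(n = n, n_perm = nrow(orders), mode = mode, seed = seed,
                 samples = samples),
            class = "accumulation_curves")
}

#' @export
print.accumulation_curves <- function(x, ...) {
  cat(sprintf("accumulation_curves: %d strains, %d orders (%s mode)\n",
              x$n, x$n_perm, x$mode))
  cat(sprintf("  pan(n) = %d, core(n) = %d\n",
              x$samples$pan[1, x$n], x$samples$core[1, x$n]))
  invisible(x)
}

#' Summary statistics of accumulation curves
#'
#' @param curves an [accumulate()] result.
#' @param statistic `"mean"` or `"median"` for the `value` column; quartiles
#'   and range are always included (box-plot-ready).
#' @return tidy data.frame with columns `curve` (pan/core/new), `k`, `value`,
#'   `mean`, `median`, `q25`, `q75`, `min`, `max`.
#' @export
curve_stats <- function(curves, statistic = c("mean", "median")) {
  stopifnot(inherits(curves, "accumulation_curves"))
  statistic <- match.arg(statistic)
  out <- lapply(names(curves$samples), function(nm) {
    s <- curves$samples[[nm]]
    data.frame(curve = nm, k = seq_len(ncol(s)),
               mean = colMeans(s),
               median = apply(s, 2, stats::median),
               q25 = apply(s, 2, stats::quantile, 0.25),
               q75 = apply(s, 2, stats::quantile, 0.75),
               min = apply(s, 2, min), max = apply(s, 2, max))
  })
  out <- do.call(rbind, out)
  out$value <- if (statistic == "mean") out$mean else out$median
  rownames(out) <- NULL
  out[, c("curve", "k", "value", "mean", "median", "q25", "q75", "min", "max")]
}
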