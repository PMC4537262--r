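#' Four-gamete compatibility of two binary characters
#'
#' Two binary characters over the same strains are compatible when at most
#' three of the four joint states (0,0), (0,1), (1,0), (1,1) are observed;
#' seeing all four is the classical four-gamete signal of homoplasy or
#' recombination.
#'
#' @param u,v binary vectors (0/1) of equal length >= 2.
#' @return `TRUE` if compatible.
#' @export
pair_compatible <- function(u, v) {
  if (length(u) != length(v)) stop("character lengths differ")
  if (length(u) < 2) stop("need at least 2 strains")
  if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1)))
    stop("characters must be binary 0/1")
  states <- unique(u * 2L + v)
  length(states) <= 3L
}

#' Pairwise compatibility summary of an ortholog matrix
#'
#' Treats each group's binary presence pattern as a character and scores
#' every pair of (optionally parsimony-informative) characters by the
#' four-gamete criterion. The permutation null shuffles each character's
#' values across strains independently — gene frequencies are preserved,
#' linkage between characters is broken — and
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param m an [ortholog_matrix()] with >= 2 strains.
#' @param informative_only keep only characters with both states in >= 2
#'   strains (default TRUE; constant or singleton characters can never be
#'   four-gamete incompatible).
#' @param n_perm permutations for the null (0 = no test).
#' @param seed permutation seed.
#' @return a `compatibility_result`: `n_characters`, `n_pairs_evaluated`,
#'   `n_incompatible`, `incompatibility_fraction`, `permutation_p` (NA when
#'   not computed).
#' @export
compatibility_summary <- function(m, informative_only = TRUE, n_perm = 0L,
                                  seed = 1L) {
  stopifnot(inherits(m, "ortholog_matrix"))
  P <- presence(m)
  n <- nrow(P)
  if (n < 2L) stop("need at least 2 strains")
  if (informative_only) {
    ones <- colSums(P)
    P <- P[, ones >= 2L & ones <= n - 2L, drop = FALSE]
  }
  frac <- function(X) {
    # joint-state presence for all column pairs via four crossproducts
    X1 <- X
    X0 <- 1L - X
    n11 <- crossprod(X1)
    n10 <- crossprod(X1, X0)
    n01 <- crossprod(X0, X1)
    n00 <- crossprod(X0)
    inc <- n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0
    ut <- upper.tri(inc)
    c(pairs = sum(ut), incompatible = sum(inc[ut]))
  }
  if (ncol(P) < 2L) {
    return(structure(list(n_characters = ncol(P), n_pairs_evaluated = 0L,
                          n_incompatible = 0L,
                          incompatibility_fraction = NA_real_,
                          permutation_p = NA_real_),
                     class = "compatibility_result"))
  }
  obs <- frac(P)
  observed_frac <- obs[["incompatible"]] / obs[["pairs"]]
  p <- NA_real_
  if (n_perm > 0L) {
    set.seed(seed)
    ge <- 0L
    for (i in seq_len(n_perm)) {
      Pi <- apply(P, 2, sample)
      nf <- frac(Pi)
      if (nf[["incompatible"]] / nf[["pairs"]] >= observed_frac) ge <- ge + 1L
    }
    p <- (1 + ge) / (1 + n_perm)
  }
  structure(list(n_characters = ncol(P),
                 n_pairs_evaluated = as.integer(obs[["pairs"]]),
                 n_incompatible = as.integer(obs[["incompatible"]]),
                 incompatibility_fraction = observed_frac,
                 permutation_p = p),
            class = "compatibility_result")
}

#' @export
print.compatibility_result <- function(x, ...) {
  cat(sprintf("compatibility_result: %d characters, %d pairs, %d incompatible (%.3f)",
              x$n_characters, x$n_pairs_evaluated, x$n_incompatible,
              x$incompatibility_fraction))
  if (!is.na(x$permutation_p)) cat(sprintf(", permutation p = %.4g", x$permutation_p))
  cat("\n")
  invisible(x)
}
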