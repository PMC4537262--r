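#' Core addition of a strain subset
#'
#' Ortholog groups conserved in every member of `subset` (binary presence)
#' and absent from every strain outside it. With `subset` equal to all
#' strains the complement condition is vacuous and the result is the core
#' genome.
#'
#' @param m an [ortholog_matrix()].
#' @param subset non-empty character vector of strain ids.
#' @return a `core_addition` object: `subset`, `groups`, `size`.
#' @export
core_addition <- function(m, subset) {
  stopifnot(inherits(m, "ortholog_matrix"))
  if (length(subset) < 1) stop("subset must be non-empty")
  bad <- setdiff(subset, m$strains)
  if (length(bad)) stop("unknown strain id(s): ", paste(bad, collapse = ", "))
  P <- presence(m)
  inside <- P[subset, , drop = FALSE]
  outside <- P[setdiff(m$strains, subset), , drop = FALSE]
  hit <- colSums(inside) == length(subset) & colSums(outside) == 0L
  structure(list(subset = subset, groups = m$groups[hit], size = sum(hit)),
            class = "core_addition")
}

#' @export
print.core_addition <- function(x, ...) {
  cat(sprintf("core_addition: %d groups specific to {%s}\n",
              x$size, paste(x$subset, collapse = ", ")))
  invisible(x)
}

#' Null distribution of core-addition sizes over random strain divisions
#'
#' Enumerates (or samples) divisions of the strains into a subset of size
#' `m_size` and its complement and reports the core-addition size of each
#' subset. The observed division of interest (e.g. a true subspecies pair)
#' can be excluded, matching the "all other random divisions" convention.
#'
#' @param m an [ortholog_matrix()].
#' @param m_size subset size, `1 <= m_size < n`.
#' @param mode `"exhaustive"` (all `choose(n, m_size)` subsets) or
#'   `"sample"`.
#' @param n_sample number of sampled subsets in sample mode.
#' @param seed seed for sample mode.
#' @param exclude optional character vector: a subset (as a strain-id set) to
#'   leave out of the enumeration.
#' @param max_exhaustive cap on `choose(n, m_size)` in exhaustive mode;
#'   above it an error instructs switching to sample mode.
#' @return a `core_addition_null`: `sizes` (integer vector), `mean`, `mode`,
#'   `n_divisions`.
#' @export
core_addition_null <- function(m, m_size, mode = c("exhaustive", "sample"),
                               n_sample = 1000L, seed = 1L, exclude = NULL,
                               max_exhaustive = 1e6) {
  stopifnot(inherits(m, "ortholog_matrix"))
  mode <- match.arg(mode)
  n <- nrow(m$occurrence)
  if (m_size < 1 || m_size >= n) stop("need 1 <= m_size < n")
  P <- presence(m)
  ca_size <- function(idx) {
    inside <- P[idx, , drop = FALSE]
    outside <- P[-idx, , drop = FALSE]
    sum(colSums(inside) == length(idx) & colSums(outside) == 0L)
  }
  excl_key <- if (!is.null(exclude))
    paste(sort(match(exclude, m$strains)), collapse = ",") else NULL
  if (mode == "exhaustive") {
    if (choose(n, m_size) > max_exhaustive)
      stop("choose(n, m_size) exceeds max_exhaustive; use mode = 'sample'")
    combos <- utils::combn(n, m_size)
    keys <- apply(combos, 2, paste, collapse = ",")
    if (!is.null(excl_key)) combos <- combos[, keys != excl_key, drop = FALSE]
    sizes <- apply(combos, 2, ca_size)
  } else {
    set.seed(seed)
    sizes <- integer(0)
    while (length(sizes) < n_sample) {
      idx <- sort(sample.int(n, m_size))
      if (!is.null(excl_key) && paste(idx, collapse = ",") == excl_key) next
      sizes <- c(sizes, ca_size(idx))
    }
  }
  structure(list(sizes = as.integer(sizes), mean = mean(sizes), mode = mode,
                 n_divisions = length(sizes)),
            class = "core_addition_null")
}

#' @export
print.core_addition_null <- function(x, ...) {
  cat(sprintf("core_addition_null: %d %s divisions, mean size %.4g (max %d)\n",
              x$n_divisions, x$mode, x$mean, max(x$sizes)))
  invisible(x)
}
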