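# Build an ortholog_matrix from a named list of gene-set vectors,
# e.g. toy_matrix(A = c("g1", "g2"), B = c("g2", "g3")).
toy_matrix <- function(...) {
  sets <- list(...)
  groups <- sort(unique(unlist(sets)))
  occ <- t(vapply(sets, function(s) as.integer(groups %in% s),
                  integer(length(groups))))
  colnames(occ) <- groups
  ortholog_matrix(occ)
}

# The 3-strain accumulation toy used across modules.
toy3 <- function() toy_matrix(A = c("g1", "g2"), B = c("g2", "g3"), C = "g2")

# Brute-force accumulation oracle: enumerate inclusion orders directly from
# gene sets, independent of the package's first-position algorithm.
oracle_curves <- function(sets, ord) {
  seen <- character(0)
  pan <- core <- newg <- integer(length(ord))
  for (k in seq_along(ord)) {
    seen_sets <- sets[ord[seq_len(k)]]
    u <- unique(unlist(seen_sets))
    pan[k] <- length(u)
    core[k] <- length(Reduce(intersect, seen_sets))
    newg[k] <- pan[k] - if (k == 1) 0L else pan[k - 1]
  }
  list(pan = pan, core = core, new = newg)
}

# All permutations of seq_len(n), brute force (test-side twin used to drive
# the oracle; independent of the package internals).
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n))
    for (p in oracle_perms(n - 1L))
      out[[length(out) + 1L]] <- c(i, seq_len(n)[-i][p])
  out
}

# Random binary matrix with informative columns, for compatibility tests.
random_binary_matrix <- function(n_strains, n_groups, seed) {
  set.seed(seed)
  occ <- matrix(rbinom(n_strains * n_groups, 1L, runif(n_groups, 0.2, 0.8)),
                n_strains, byrow = FALSE)
  occ <- occ[, colSums(occ) > 0, drop = FALSE]
  colnames(occ) <- paste0("g", seq_len(ncol(occ)))
  ortholog_matrix(occ)
}
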