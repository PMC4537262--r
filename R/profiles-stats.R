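#' GC content of a sequence set
#'
#' (G + C) / (A + C + G + T) pooled over all sequences; ambiguous bases are
#' excluded from the denominator. Case-insensitive, strand-symmetric.
#'
#' @param sequences a [Biostrings::DNAStringSet], [Biostrings::DNAString],
#'   character vector, or FASTA path.
#' @return fraction in `[0, 1]`, or `NA` (with a warning) when no
#'   unambiguous bases exist.
#' @export
gc_content <- function(sequences) {
  sequences <- as_dnastringset(sequences)
  if (sum(Biostrings::width(sequences)) == 0) stop("empty sequence")
  freq <- colSums(Biostrings::alphabetFrequency(sequences, baseOnly = TRUE))
  denom <- sum(freq[c("A", "C", "G", "T")])
  if (denom == 0) {
    warning("no unambiguous bases; GC content undefined")
    return(NA_real_)
  }
  unname(sum(freq[c("G", "C")]) / denom)
}

# Exact two-sided Mann-Whitney U with midranks, by enumeration of all
# C(n1+n2, n1) group assignments; used when min(n1, n2) <= exact_max.
# stats::wilcox.test refuses exact p-values under ties, hence the in-house
# enumeration (cross-checked against wilcox.test on tie-free data in tests).
mann_whitney_exact <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  # two-sided: arrangements at least as extreme (in |U - mean|) as observed
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

mann_whitney <- function(x, y, exact_max = 8L) {
  n1 <- length(x)
  n2 <- length(y)
  if (min(n1, n2) <= exact_max && choose(n1 + n2, n1) <= 1e6) {
    p <- mann_whitney_exact(x, y)
    method <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    method <- "normal-approx"
  }
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(U = U, p = p, method = method)
}

#' Genome length summary and group comparison
#'
#' Per-genome length is the sum of contig lengths. When `groups` labels are
#' supplied, each pair of labels is compared with a two-sided Mann-Whitney U
#' test (exact enumeration with midrank ties for small samples, normal
#' approximation otherwise).
#'
#' @param lengths named numeric vector of genome lengths, or a named list of
#'   sequence sets whose contig lengths are summed.
#' @param groups optional factor/character of group labels aligned with
#'   `lengths`.
#' @return list with `lengths`, `median`, and `comparisons` (data.frame of
#'   pairwise tests, or `NULL`).
#' @export
length_summary <- function(lengths, groups = NULL) {
  if (is.list(lengths))
    lengths <- vapply(lengths,
                      function(s) sum(Biostrings::width(as_dnastringset(s))),
                      numeric(1))
  if (length(lengths) < 1) stop("need at least one genome")
  out <- list(lengths = lengths, median = stats::median(lengths),
              comparisons = NULL)
  if (!is.null(groups)) {
    groups <- as.character(groups)
    labs <- unique(groups)
    rows <- list()
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (i >= j) next
      xi <- lengths[groups == labs[i]]
      yj <- lengths[groups == labs[j]]
      if (!length(xi) || !length(yj)) next
      mw <- mann_whitney(xi, yj)
      rows[[length(rows) + 1L]] <-
        data.frame(group1 = labs[i], group2 = labs[j],
                   n1 = length(xi), n2 = length(yj),
                   U = mw$U, p = mw$p, method = mw$method)
    }
    if (length(rows)) out$comparisons <- do.call(rbind, rows)
  }
  out
}

#' Glycoside hydrolase family profile
#'
#' A strains x GH-family count matrix with an exclusion list (default
#' families 23, 25, 73, 103 — peptidoglycan hydrolases/lyases whose counts
#' track prophage load rather than metabolic capability) and optional
#' subspecies labels.
#'
#' @param counts strains x family matrix (family names like `"GH23"` or
#'   bare numbers).
#' @param subspecies optional labels aligned with rows.
#' @param excluded_families families removed from the analysis matrix.
#' @return a `family_profile`.
#' @export
family_profile <- function(counts,
                           subspecies = NULL,
                           excluded_families = c("GH23", "GH25", "GH73", "GH103")) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("family counts need column names")
  norm <- function(f) ifelse(grepl("^[0-9]+$", f), paste0("GH", f), f)
  colnames(counts) <- norm(colnames(counts))
  excluded_families <- norm(excluded_families)
  keep <- !(colnames(counts) %in% excluded_families)
  structure(list(counts = counts[, keep, drop = FALSE],
                 excluded_families = excluded_families,
                 subspecies = subspecies),
            class = "family_profile")
}

#' PCA of a GH family profile
#'
#' Families are always mean-centered; with `scaled = TRUE` they are also
#' scaled to unit variance (zero-variance families are dropped first, with a
#' warning). Component signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param profile a [family_profile()] with >= 3 strains and >= 2 usable
#'   families.
#' @param scaled unit-variance scaling (default TRUE).
#' @return list with `scores` (strain coordinates), `loadings`,
#'   `sdev`, `var_explained`.
#' @export
gh_pca <- function(profile, scaled = TRUE) {
  stopifnot(inherits(profile, "family_profile"))
  X <- profile$counts
  if (nrow(X) < 3) stop("need at least 3 strains")
  if (scaled) {
    v <- apply(X, 2, stats::var)
    if (any(v == 0)) {
      warning("dropping zero-variance families: ",
              paste(colnames(X)[v == 0], collapse = ", "))
      X <- X[, v > 0, drop = FALSE]
    }
  }
  if (ncol(X) < 2) stop("fewer than 2 usable families")
  pc <- stats::prcomp(X, center = TRUE, scale. = scaled)
  for (j in seq_len(ncol(pc$rotation))) {
    top <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[top, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Per-family Kruskal-Wallis tests across subspecies
#'
#' Tests each family's count distribution across the profile's groups;
#' p-values are Holm-Bonferroni adjusted and families with adjusted p < 0.05
#' are flagged non-uniform. Constant families get p = 1 by convention.
#'
#' @param profile a [family_profile()] with subspecies labels; needs >= 2
#'   groups with >= 2 strains each.
#' @return data.frame: family, p, p_adjusted, non_uniform.
#' @export
family_distribution_test <- function(profile) {
  stopifnot(inherits(profile, "family_profile"))
  g <- profile$subspecies
  if (is.null(g)) stop("profile has no subspecies labels")
  g <- factor(g)
  sizes <- table(g)
  if (sum(sizes >= 2) < 2) stop("need >= 2 groups with >= 2 strains each")
  p <- apply(profile$counts, 2, function(x) {
    if (length(unique(x)) == 1L) return(1)
    stats::kruskal.test(x, g)$p.value
  })
  padj <- stats::p.adjust(p, method = "holm")
  data.frame(family = colnames(profile$counts), p = p, p_adjusted = padj,
             non_uniform = padj < 0.05, row.names = NULL)
}

#' Functional-class enrichment across pan-genome partitions
#'
#' For each functional class and each partition cell (core / moderate /
#' rare), a 2x2 Fisher exact test (class vs all other classes, cell vs rest
#' of the pan-genome) among annotated groups only; Benjamini-Hochberg
#' adjustment across all class x cell tests.
#'
#' @param m an [ortholog_matrix()] whose `group_meta` has a `class` column
#'   (`NA` = unannotated, excluded from the universe).
#' @param partition a [partition_groups()] result for `m`.
#' @param q_threshold significance cutoff on the BH q-value (default 0.05).
#' @return an `enrichment_table` data.frame: class, cell, in_class_in_cell,
#'   in_class_out_cell, out_class_in_cell, out_class_out_cell, odds_ratio,
#'   p, q, significant, direction.
#' @export
partition_enrichment <- function(m, partition, q_threshold = 0.05) {
  stopifnot(inherits(m, "ortholog_matrix"), inherits(partition, "group_partition"))
  meta <- m$group_meta
  if (is.null(meta) || is.null(meta$class)) stop("matrix has no class labels")
  lab <- meta$class[match(m$groups, meta$group)]
  keep <- !is.na(lab) & nzchar(lab)
  groups <- m$groups[keep]
  lab <- lab[keep]
  if (!length(groups)) {
    out <- data.frame(class = character(0), cell = character(0))
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  cellof <- rep(NA_character_, length(groups))
  for (cell in c("core", "moderate", "rare"))
    cellof[groups %in% partition[[cell]]] <- cell
  rows <- list()
  for (cl in unique(lab)) for (cell in c("core", "moderate", "rare")) {
    a <- sum(lab == cl & cellof == cell)
    b <- sum(lab == cl & cellof != cell)
    c_ <- sum(lab != cl & cellof == cell)
    d <- sum(lab != cl & cellof != cell)
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl, cell = cell,
      in_class_in_cell = a, in_class_out_cell = b,
      out_class_in_cell = c_, out_class_out_cell = d,
      odds_ratio = unname(ft$estimate), p = ft$p.value)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_threshold
  out$direction <- ifelse(out$odds_ratio > 1, "over", "under")
  class(out) <- c("enrichment_table", "data.frame")
  out
}
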