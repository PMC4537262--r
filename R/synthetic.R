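#' Specification of a synthetic pan-genome matrix
#'
#' A generative description of a binary pan-genome with a fixed core and one
#' of two accessory models:
#'
#' * `"beta"` — each of `n_accessory` accessory groups draws a population
#'   frequency p ~ Beta(a, b); presence is then Bernoulli(p) independently per
#'   strain. Tuning (a, b) shapes the accessory gene-frequency spectrum
#'   (U-shaped at a, b < 1).
#' * `"open-stream"` — each strain (in the fixed order S1..Sn) seeds `theta`
#'   new candidate groups; each is present in the seeding strain and retained
#'   in every later strain independently with probability `f`. This yields
#'   Heaps-like accumulation with a tunable openness exponent.
#'
#' @param n_strains positive integer.
#' @param n_core non-negative integer; core groups are present in all strains.
#' @param model `"beta"`, `"open-stream"`, or `"none"`.
#' @param a,b,n_accessory Beta-spectrum parameters.
#' @param theta,f open-stream parameters: genes seeded per strain and the
#'   per-later-strain retention probability.
#' @param category_labels optional character vector recycled over groups and
#'   stored as the `class` column of the group metadata.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a `pangenome_spec`.
#' @export
pangenome_spec <- function(n_strains, n_core = 0L,
                           model = c("none", "beta", "open-stream"),
                           a = 1, b = 1, n_accessory = 0L,
                           theta = 120, f = 0.25,
                           category_labels = NULL, seed = 1L) {
  model <- match.arg(model)
  if (!is.numeric(n_strains) || length(n_strains) != 1 || n_strains < 1 ||
      n_strains != round(n_strains))
    stop("n_strains must be a positive integer")
  if (n_core < 0 || n_core != round(n_core))
    stop("n_core must be a non-negative integer")
  if (model == "beta" && (a <= 0 || b <= 0 || n_accessory < 0))
    stop("beta model needs a > 0, b > 0, n_accessory >= 0")
  if (model == "open-stream" && (theta < 0 || f < 0 || f > 1))
    stop("open-stream model needs theta >= 0 and f in [0, 1]")
  structure(list(n_strains = as.integer(n_strains), n_core = as.integer(n_core),
                 model = model, a = a, b = b,
                 n_accessory = as.integer(n_accessory),
                 theta = theta, f = f,
                 category_labels = category_labels, seed = as.integer(seed)),
            class = "pangenome_spec")
}

#' Simulate a pan-genome occurrence matrix
#'
#' Accessory presence is sampled independently per strain per group: strains
#' are exchangeable (for the beta model) just as the permutation accumulation
#' machinery assumes. Accessory groups that end up in no strain are dropped
#' (the occurrence matrix carries no all-zero columns); the ground-truth
#' record retains them.
#'
#' @param spec a [pangenome_spec()].
#' @return list with `matrix` (an [ortholog_matrix()]) and `truth`
#'   (data.frame: group, origin core/accessory, true frequency used, and for
#'   open-stream the seeding strain).
#' @export
simulate_pangenome <- function(spec) {
  stopifnot(inherits(spec, "pangenome_spec"))
  set.seed(spec$seed)
  n <- spec$n_strains
  strains <- paste0("S", seq_len(n))

  core <- matrix(1L, n, spec$n_core)
  core_truth <- data.frame(origin = rep("core", spec$n_core),
                           freq = rep(1, spec$n_core),
                           seeded_by = rep(NA_character_, spec$n_core))

  if (spec$model == "beta" && spec$n_accessory > 0L) {
    p <- stats::rbeta(spec$n_accessory, spec$a, spec$b)
    acc <- matrix(stats::rbinom(n * spec$n_accessory, 1L, rep(p, each = n)),
                  nrow = n)
    acc_truth <- data.frame(origin = "accessory", freq = p,
                            seeded_by = NA_character_)
  } else if (spec$model == "open-stream" && spec$theta > 0) {
    theta <- as.integer(round(spec$theta))
    acc <- matrix(0L, n, theta * n)
    seeded <- character(theta * n)
    for (j in seq_len(n)) {
      cols <- (j - 1L) * theta + seq_len(theta)
      acc[j, cols] <- 1L
      if (j < n) {
        later <- (j + 1L):n
        acc[later, cols] <- matrix(
          stats::rbinom(length(later) * theta, 1L, spec$f), length(later))
      }
      seeded[cols] <- strains[j]
    }
    acc_truth <- data.frame(origin = "accessory",
                            freq = NA_real_, seeded_by = seeded)
  } else {
    acc <- matrix(0L, n, 0L)
    acc_truth <- core_truth[0, ]
  }

  occ <- cbind(core, acc)
  truth <- rbind(core_truth, acc_truth)
  truth$group <- group_ids(ncol(occ))
  keep <- colSums(occ) > 0L
  occ <- occ[, keep, drop = FALSE]
  rownames(occ) <- strains
  colnames(occ) <- truth$group[keep]
  meta <- NULL
  if (!is.null(spec$category_labels)) {
    meta <- data.frame(group = colnames(occ),
                       class = rep_len(spec$category_labels, ncol(occ)))
  }
  list(matrix = ortholog_matrix(occ, meta),
       truth = truth[, c("group", "origin", "freq", "seeded_by")])
}

#' Specification of a divergent genome pair
#'
#' @param length ancestor length in bp (>= 1).
#' @param substitution_rate per-site substitution probability in `[0, 1]`;
#'   substituted sites take one of the 3 alternative bases uniformly.
#' @param gc_fraction ancestor GC fraction in `[0, 1]` (G and C equiprobable).
#' @param indel_rate per-site probability of a 1-bp indel event in `[0, 1]`
#'   (deletion or insertion with equal odds).
#' @param seed integer seed.
#' @return a `seqpair_spec`.
#' @export
seqpair_spec <- function(length, substitution_rate = 0, gc_fraction = 0.5,
                         indel_rate = 0, seed = 1L) {
  if (!is.numeric(length) || length < 1)
    stop("length must be >= 1")
  for (r in c(substitution_rate, gc_fraction, indel_rate))
    if (r < 0 || r > 1) stop("rates and fractions must lie in [0, 1]")
  structure(list(length = as.integer(length),
                 substitution_rate = substitution_rate,
                 gc_fraction = gc_fraction, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "seqpair_spec")
}

#' Simulate an ancestor/derived genome pair
#'
#' The derived sequence applies i.i.d. substitutions (uniform over the three
#' alternative bases) and optional single-base indels to the ancestor. With
#' both rates zero the two sequences are identical.
#'
#' @param spec a [seqpair_spec()].
#' @return a [Biostrings::DNAStringSet] of two sequences, `ancestor` and
#'   `derived`.
#' @export
simulate_genome_pair <- function(spec) {
  stopifnot(inherits(spec, "seqpair_spec"))
  set.seed(spec$seed)
  n <- spec$length
  gc <- spec$gc_fraction
  anc <- sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  der <- anc
  sub <- which(stats::runif(n) < spec$substitution_rate)
  if (length(sub)) {
    alt <- matrix(c("C","G","T", "A","C","G", "A","C","T", "A","G","T"),
                  nrow = 3,
                  dimnames = list(NULL, c("A","T","G","C")))
    pick <- sample.int(3L, length(sub), replace = TRUE)
    der[sub] <- alt[cbind(pick, match(der[sub], colnames(alt)))]
  }
  if (spec$indel_rate > 0) {
    ev <- which(stats::runif(n) < spec$indel_rate)
    if (length(ev)) {
      dele <- stats::runif(length(ev)) < 0.5
      pieces <- der
      pieces[ev[dele]] <- ""
      ins <- ev[!dele]
      if (length(ins))
        pieces[ins] <- paste0(pieces[ins],
                              sample(c("A","C","G","T"), length(ins),
                                     replace = TRUE))
      der <- pieces
    }
  }
  out <- Biostrings::DNAStringSet(c(ancestor = paste(anc, collapse = ""),
                                    derived = paste(der, collapse = "")))
  out
}
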