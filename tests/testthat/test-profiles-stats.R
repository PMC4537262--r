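test_that("gc_content handles composition, ambiguity, case and strand", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATATNN"), 0.0)       # denominator 4
  expect_equal(gc_content("acgt"), 0.5)
  s <- Biostrings::DNAStringSet(c("ACGTGC", "AATT"))
  expect_equal(gc_content(s), 4 / 10)
  expect_equal(gc_content(Biostrings::reverseComplement(s)), gc_content(s))
  expect_equal(gc_content(rev(as.character(s))), gc_content(s))
  expect_warning(expect_true(is.na(gc_content("NNNN"))), "undefined")
  expect_error(gc_content(Biostrings::DNAStringSet("")), "empty")
})

test_that("length_summary sums contigs and runs the exact Mann-Whitney test", {
  seqs <- list(gA = Biostrings::DNAStringSet(c(strrep("A", 100), strrep("C", 50))))
  res <- length_summary(seqs)
  expect_equal(unname(res$lengths), 150)
  # exact two-sided p for {1,2,3} vs {4,5,6}: U = 0, p = 2/20
  res2 <- length_summary(c(1, 2, 3, 4, 5, 6),
                         groups = rep(c("a", "b"), each = 3))
  expect_equal(res2$comparisons$p, 0.1)
  expect_equal(res2$comparisons$method, "exact")
  # tie-free exact enumeration agrees with wilcox.test's exact p
  set.seed(14)
  x <- rnorm(5); y <- rnorm(6) + 1
  res3 <- length_summary(c(x, y), groups = rep(c("a", "b"), c(5, 6)))
  expect_equal(res3$comparisons$p, stats::wilcox.test(x, y, exact = TRUE)$p.value)
  # midrank ties do not break the exact path
  res4 <- length_summary(c(1, 1, 2, 2, 3, 3), groups = rep(c("a", "b"), 3))
  expect_true(res4$comparisons$p > 0 && res4$comparisons$p <= 1)
  expect_equal(res4$comparisons$method, "exact")
})

test_that("family_profile applies the default exclusion list", {
  counts <- matrix(1:24, 4, 6,
                   dimnames = list(paste0("S", 1:4),
                                   c("GH13", "GH23", "GH25", "GH73", "GH103", "GH42")))
  pr <- family_profile(counts)
  expect_equal(colnames(pr$counts), c("GH13", "GH42"))
  # bare numeric family labels are normalized
  pr2 <- family_profile(matrix(1:8, 4, 2, dimnames = list(NULL, c("23", "13"))),
                        excluded_families = c("23", "25", "73", "103"))
  expect_equal(colnames(pr2$counts), "GH13")
})

test_that("gh_pca is deterministic, sign-fixed and separates constructed clusters", {
  # identical profiles -> zero variance everywhere
  X <- matrix(rep(c(3, 1, 4, 2), each = 5), 5, 4,
              dimnames = list(paste0("S", 1:5), paste0("GH", 1:4)))
  pr <- family_profile(X)
  expect_error(expect_warning(gh_pca(pr), "zero-variance"), "usable")
  p0 <- gh_pca(pr, scaled = FALSE)
  expect_true(all(abs(p0$sdev) < 1e-12))
  # 3 clusters with disjoint family usage separate in PC1/PC2
  set.seed(31)
  mk <- function(cols, n) {
    M <- matrix(rpois(n * 6, 0.2), n, 6)
    M[, cols] <- M[, cols] + matrix(rpois(n * 2, 8), n, 2)
    M
  }
  X3 <- rbind(mk(1:2, 4), mk(3:4, 4), mk(5:6, 4))
  dimnames(X3) <- list(paste0("S", 1:12), paste0("GH", 1:6))
  lab <- rep(1:3, each = 4)
  pca <- gh_pca(family_profile(X3), scaled = TRUE)
  xy <- pca$scores[, 1:2]
  d <- as.matrix(stats::dist(xy))
  sil <- sapply(seq_len(12), function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(12) != i])
    b <- min(sapply(setdiff(1:3, lab[i]), function(g) mean(d[i, lab == g])))
    (b - a) / max(a, b)
  })
  expect_gt(mean(sil), 0.5)
  # strain reordering only permutes scores (up to the fixed sign convention)
  ord <- sample(12)
  pca2 <- gh_pca(family_profile(X3[ord, ]), scaled = TRUE)
  expect_equal(abs(pca2$scores[order(ord), 1:2]), abs(xy), tolerance = 1e-9)
})

test_that("family_distribution_test flags constructed non-uniform families", {
  counts <- cbind(GH1 = c(rep(0, 5), 5:9, c(0, 0, 0, 0, 1)),
                  GH2 = rep(2, 15),
                  GH3 = rep(c(1, 2, 1), 5))
  rownames(counts) <- paste0("S", 1:15)
  pr <- family_profile(counts, subspecies = rep(c("a", "b", "c"), each = 5))
  res <- family_distribution_test(pr)
  expect_equal(res$p[res$family == "GH2"], 1)           # constant -> p = 1
  expect_equal(which.min(res$p), which(res$family == "GH1"))
  # Holm adjustment is monotone, bounded by 1, matches the direct formula
  expect_true(all(res$p_adjusted >= res$p & res$p_adjusted <= 1))
  expect_equal(res$p_adjusted, stats::p.adjust(res$p, "holm"))
  expect_true(res$non_uniform[res$family == "GH1"])
  expect_false(res$non_uniform[res$family == "GH2"])
})

test_that("partition_enrichment computes exact Fisher tables with BH control", {
  # construct a matrix whose annotated 2x2 table for class X in core is
  # [[10, 0], [0, 10]]: 10 core groups of class X, 10 rare groups of class Y
  n <- 4
  core_block <- matrix(1L, n, 20)
  rare_block <- rbind(matrix(0L, n - 1, 10), matrix(1L, 1, 10))
  occ <- cbind(core_block[, 1:10], rare_block)
  colnames(occ) <- paste0("G", 1:20)
  rownames(occ) <- paste0("S", 1:n)
  meta <- data.frame(group = colnames(occ), class = rep(c("X", "Y"), each = 10))
  m <- ortholog_matrix(occ, meta)
  part <- partition_groups(m)
  tab <- partition_enrichment(m, part)
  row <- tab[tab$class == "X" & tab$cell == "core", ]
  expect_equal(row$in_class_in_cell, 10)
  expect_equal(row$out_class_out_cell, 10)
  # hypergeometric enumeration oracle: 2 * 1 / choose(20, 10)
  expect_equal(row$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(all(tab$q >= tab$p - 1e-12))
  expect_equal(tab$q, stats::p.adjust(tab$p, "BH"))
  # uniform labels -> nothing significant
  meta_u <- data.frame(group = colnames(occ), class = rep(c("X", "Y"), 10))
  m_u <- ortholog_matrix(occ, meta_u)
  tab_u <- partition_enrichment(m_u, partition_groups(m_u))
  expect_false(any(tab_u$significant))
  # unlabeled groups are excluded from the universe
  meta_na <- meta
  meta_na$class[1:5] <- NA
  m_na <- ortholog_matrix(occ, meta_na)
  tab_na <- partition_enrichment(m_na, partition_groups(m_na))
  expect_equal(sum(tab_na[tab_na$class == "X" & tab_na$cell == "core",
                          c("in_class_in_cell", "in_class_out_cell")]), 5)
})
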