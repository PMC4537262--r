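test_that("read_groups parses counts, rosters and malformed input", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("G1: A|x A|y B|z", "G2: B|w|pipe.in.gene.id"), path)
  m <- read_groups(path)
  expect_equal(m$occurrence["A", "G1"], 2L)
  expect_equal(m$occurrence["B", "G1"], 1L)
  expect_equal(m$occurrence["B", "G2"], 1L)
  expect_equal(m$occurrence["A", "G2"], 0L)
  # empty file + roster -> 2 x 0 matrix
  writeLines(character(0), path)
  m0 <- read_groups(path, strain_roster = c("A", "B"))
  expect_equal(dim(m0$occurrence), c(2L, 0L))
  expect_equal(m0$strains, c("A", "B"))
  # malformed lines name the line number
  writeLines(c("G1: A|x", "G2 no colon here"), path)
  expect_error(read_groups(path), "line 2")
  writeLines(c("G1: A|x", "G2: token_without_pipe"), path)
  expect_error(read_groups(path), "line 2")
})

test_that("hand-written toy file reproduces the hand matrix", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("OG1: S1|a S2|b S3|c",
               "OG2: S1|d S3|e",
               "OG3: S2|f",
               "OG4: S3|g S3|h"), path)
  m <- read_groups(path)
  hand <- matrix(c(1L, 1L, 1L,
                   1L, 0L, 1L,
                   0L, 1L, 0L,
                   0L, 0L, 2L),
                 nrow = 3,
                 dimnames = list(c("S1", "S2", "S3"),
                                 c("OG1", "OG2", "OG3", "OG4")))
  expect_identical(m$occurrence[rownames(hand), colnames(hand)], hand)
})

test_that("TSV matrix round trip preserves the matrix", {
  sim <- simulate_pangenome(pangenome_spec(5, 3, "beta", n_accessory = 30, seed = 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(sim$matrix, path)
  back <- read_matrix_tsv(path)
  expect_identical(back$occurrence, sim$matrix$occurrence)
})

test_that("partition_groups follows the core/moderate/rare rule", {
  m <- toy3()   # A={g1,g2}, B={g2,g3}, C={g2}
  p <- partition_groups(m)
  expect_equal(p$core, "g2")
  expect_equal(sort(p$rare), c("g1", "g3"))
  expect_length(p$moderate, 0)
  # n = 1: core wins over rare
  m1 <- ortholog_matrix(matrix(1L, 1, 2, dimnames = list("A", c("g1", "g2"))))
  p1 <- partition_groups(m1)
  expect_equal(sort(p1$core), c("g1", "g2"))
  expect_length(p1$rare, 0)
})

test_that("partition cells are disjoint and exhaustive on random matrices", {
  for (seed in 1:5) {
    m <- random_binary_matrix(8, 60, seed)
    p <- partition_groups(m)
    all_ids <- c(p$core, p$moderate, p$rare)
    expect_equal(sort(all_ids), sort(m$groups))
    expect_equal(anyDuplicated(all_ids), 0L)
  }
})

test_that("shared_matrix counts overlaps and merges the closest pair first", {
  # A and B share 2 groups; C shares 1 with each
  m <- toy_matrix(A = c("g1", "g2", "g3"), B = c("g1", "g2", "g4"),
                  C = c("g1", "g5"))
  sh <- shared_matrix(m)
  expect_equal(sh$shared["A", "B"], 2L)
  expect_equal(sh$shared["A", "C"], 1L)
  expect_equal(sh$shared["B", "C"], 1L)
  expect_equal(diag(sh$shared), c(A = 3L, B = 3L, C = 2L))
  expect_identical(sh$shared, t(sh$shared))
  # shared(A,B) <= min of per-strain counts
  expect_true(all(sh$shared <= outer(diag(sh$shared), diag(sh$shared), pmin)))
  # complete linkage merges A,B first: C attaches at larger height
  tr <- ape::read.tree(text = sh$newick)
  ab <- ape::getMRCA(tr, c("A", "B"))
  expect_gt(ape::node.depth.edgelength(tr)[ab],
            ape::node.depth.edgelength(tr)[ape::getMRCA(tr, c("A", "C"))])
  # identical strains: distance 0
  m2 <- toy_matrix(A = c("g1", "g2"), B = c("g1", "g2"))
  sh2 <- shared_matrix(m2)
  expect_equal(sh2$shared["A", "B"], 2L)
  # single strain: matrix returned, tree undefined
  sh1 <- shared_matrix(toy_matrix(A = "g1"))
  expect_null(sh1$tree)
  expect_equal(unname(sh1$shared), matrix(1L, 1, 1))
})

test_that("select_marker_loci applies spacing and largest-gene rules", {
  ann <- data.frame(
    gene = c("a", "b"), strain = "ref", contig = "c1",
    start = c(1000, 50000), end = c(2000, 51000))
  expect_equal(select_marker_loci(ann, c("a", "b")), c("a", "b"))
  ann2 <- data.frame(
    gene = c("a", "b"), strain = "ref", contig = "c1",
    start = c(1000, 5000), end = c(2000, 7500))
  expect_equal(select_marker_loci(ann2, c("a", "b")), "b")   # 2501 bp wins
  ann3 <- data.frame(
    gene = c("x", "y", "z"), strain = "ref", contig = "c1",
    start = c(1000, 3000, 6000), end = c(1899, 4199, 7099))  # 900/1200/1100
  expect_equal(select_marker_loci(ann3, c("x", "y", "z")), "y")
  # invariant to candidate ordering
  expect_equal(select_marker_loci(ann3, c("z", "x", "y")), "y")
  # genes on different contigs never conflict
  ann4 <- data.frame(gene = c("p", "q"), strain = "ref",
                     contig = c("c1", "c2"), start = c(1, 1), end = c(900, 900))
  expect_equal(sort(select_marker_loci(ann4, c("p", "q"))), c("p", "q"))
  # candidate without coordinates is named in the error
  expect_error(select_marker_loci(ann4, c("p", "missing")), "missing")
})

test_that("select_marker_loci keeps pairwise gaps above min_spacing", {
  set.seed(21)
  n <- 40
  starts <- sort(sample.int(2e5, n))
  ann <- data.frame(gene = paste0("g", 1:n), strain = "ref", contig = "c1",
                    start = starts,
                    end = starts + sample(200:3000, n, replace = TRUE))
  kept <- select_marker_loci(ann, ann$gene, min_spacing = 10000)
  k <- ann[match(kept, ann$gene), ]
  if (nrow(k) > 1) {
    k <- k[order(k$start), ]
    gaps <- k$start[-1] - k$end[-nrow(k)] - 1
    expect_true(all(gaps > 10000))
  }
  expect_gt(length(kept), 0)
})
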