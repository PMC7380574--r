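two_block_matrix <- function() {
  ids <- c("a1", "a2", "b1", "b2")
  m <- matrix(1, 4, 4, dimnames = list(ids, ids))
  m[1:2, 1:2] <- 0
  m[3:4, 3:4] <- 0
  diag(m) <- 0
  m
}

test_that("linkage trees merge as hand agglomeration predicts", {
  ids <- c("x", "y")
  m <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(ids, ids))
  dend <- build_linkage(m)
  expect_equal(dend$height, 0.4)

  dend2 <- build_linkage(two_block_matrix(), "average")
  expect_equal(sort(dend2$height), c(0, 0, 1))
  expect_equal(max(dend2$height), 1)

  expect_error(build_linkage(matrix(c(0, 1, 2, 0), 2,
                                    dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("permuting genome order leaves merge heights and partitions unchanged", {
  withr::with_seed(77, {
    n <- 8
    ids <- paste0("g", 1:n)
    m <- matrix(runif(n * n, 0.05, 0.6), n, n, dimnames = list(ids, ids))
    m <- (m + t(m)) / 2
    diag(m) <- 0
    perm <- sample(n)
    mp <- m[perm, perm]
    d1 <- build_linkage(m); d2 <- build_linkage(mp)
    expect_equal(sort(d1$height), sort(d2$height))
    f1 <- flat_clusters(d1, precluster_config(criterion = "distance",
                                              threshold = 0.3))
    f2 <- flat_clusters(d2, precluster_config(criterion = "distance",
                                              threshold = 0.3))
    f2 <- f2[match(f1$genome_id, f2$genome_id), ]
    # same partition up to label names
    expect_equal(length(unique(f1$precluster)), length(unique(f2$precluster)))
    expect_equal(length(unique(paste(f1$precluster, f2$precluster))),
                 length(unique(f1$precluster)))
  })
})

test_that("inconsistency coefficients follow the depth-limited sample formula", {
  # three leaves: a-b at 0.1, c at 0.3 -> merges at 0.1 then 0.3;
  # top coefficient = (0.3 - mean(0.1, 0.3)) / sd(0.1, 0.3) = 0.7071
  ids <- c("a", "b", "c")
  m <- matrix(c(0, .1, .3, .1, 0, .3, .3, .3, 0), 3, dimnames = list(ids, ids))
  dend <- build_linkage(m)
  coef <- inconsistency_coefficients(dend, depth = 2)
  expect_equal(coef[1], 0)  # leaf-only merge: single observation
  expect_equal(coef[2], (0.3 - 0.2) / sd(c(0.1, 0.3)), tolerance = 1e-12)

  # all merge heights equal -> all coefficients zero
  m2 <- two_block_matrix() * 0 + 0.2
  diag(m2) <- 0
  expect_equal(inconsistency_coefficients(build_linkage(m2), 2),
               rep(0, 3))
})

test_that("inconsistency statistics match the SciPy reference on a random matrix", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  withr::with_seed(123, {
    n <- 7
    ids <- paste0("g", 1:n)
    m <- matrix(runif(n * n, 0, 1), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(ids, ids)
  })
  dend <- build_linkage(m, "average")
  coef <- inconsistency_coefficients(dend, depth = 2)
  labels <- flat_clusters(dend, precluster_config(threshold = 1.0))

  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(m, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- paste(
    "import numpy as np, sys",
    "from scipy.cluster.hierarchy import linkage, inconsistent, fcluster",
    "from scipy.spatial.distance import squareform",
    sprintf("m = np.loadtxt('%s', delimiter=',')", csv),
    "Z = linkage(squareform(m), method='average')",
    "R = inconsistent(Z, d=2)",
    "f = fcluster(Z, t=1.0, criterion='inconsistent', depth=2)",
    "print(','.join('%.10f' % v for v in sorted(R[:,3])))",
    "print(','.join(str(v) for v in f))",
    sep = "\n")
  out <- system2(py, c("-c", shQuote(script)), stdout = TRUE)
  ref_coef <- as.numeric(strsplit(out[1], ",")[[1]])
  ref_lab <- as.integer(strsplit(out[2], ",")[[1]])
  expect_equal(sort(coef), ref_coef, tolerance = 1e-8)
  # same flat partition up to label permutation (scipy labels leaves in the
  # lexicographic order build_linkage sorts into)
  mine <- labels$precluster[match(sort(labels$genome_id), labels$genome_id)]
  expect_equal(length(unique(mine)), length(unique(ref_lab)))
  expect_equal(length(unique(paste(mine, ref_lab))), length(unique(mine)))
})

test_that("flat cluster extraction cuts where the criterion says", {
  m <- two_block_matrix()
  dend <- build_linkage(m)
  f <- flat_clusters(dend, precluster_config(criterion = "distance",
                                             threshold = 0.05))
  expect_equal(length(unique(f$precluster)), 2)
  expect_equal(f$precluster[f$genome_id == "a1"], f$precluster[f$genome_id == "a2"])
  # threshold above every coefficient: one cluster
  f2 <- flat_clusters(dend, precluster_config(threshold = 100))
  expect_equal(unique(f2$precluster), 1L)
})

test_that("preclustering is a partition and passes singletons through", {
  expect_equal(precluster(make_genome("only", rand_seq(5000, 1))),
               tibble::tibble(genome_id = "only", precluster = 1L))
  g <- dplyr::bind_rows(make_genome("a", rand_seq(40000, 1)),
                        make_genome("a2", rand_seq(40000, 1)),
                        make_genome("b", rand_seq(40000, 2)))
  pc <- precluster(g, config = precluster_config(criterion = "distance",
                                                 threshold = 0.1))
  expect_setequal(pc$genome_id, c("a", "a2", "b"))
  expect_equal(anyDuplicated(pc$genome_id), 0)
  expect_equal(pc$precluster[pc$genome_id == "a"],
               pc$precluster[pc$genome_id == "a2"])
  expect_false(pc$precluster[pc$genome_id == "b"] ==
                 pc$precluster[pc$genome_id == "a"])
})

test_that("lowering a distance threshold only refines the partition", {
  withr::with_seed(31, {
    for (trial in 1:5) {
      n <- 10
      ids <- paste0("g", 1:n)
      m <- matrix(runif(n * n, 0, 0.5), n, n)
      m <- (m + t(m)) / 2; diag(m) <- 0
      dimnames(m) <- list(ids, ids)
      dend <- build_linkage(m)
      coarse <- flat_clusters(dend, precluster_config(criterion = "distance",
                                                      threshold = 0.3))
      fine <- flat_clusters(dend, precluster_config(criterion = "distance",
                                                    threshold = 0.15))
      joined <- dplyr::inner_join(coarse, fine, by = "genome_id")
      # every fine cluster maps into exactly one coarse cluster
      split_map <- unique(joined[c("precluster.x", "precluster.y")])
      expect_equal(anyDuplicated(split_map$precluster.y), 0)
    }
  })
})

test_that("planted partitions are recovered from separated distance blocks", {
  withr::with_seed(90, {
    for (trial in 1:20) {
      sizes <- sample(2:4, 3, replace = TRUE)
      lab <- rep(seq_along(sizes), sizes)
      n <- length(lab)
      ids <- paste0("g", seq_len(n))
      m <- matrix(0, n, n, dimnames = list(ids, ids))
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        d <- if (lab[i] == lab[j]) runif(1, 0, 0.009) else runif(1, 0.16, 0.4)
        m[i, j] <- m[j, i] <- d
      }
      dend <- build_linkage(m)
      f <- flat_clusters(dend, precluster_config(criterion = "distance",
                                                 threshold = 0.05),
                         genome_order = ids)
      expect_equal(f$precluster[match(ids, f$genome_id)],
                   as.integer(factor(lab, levels = unique(lab))))
    }
  })
})
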