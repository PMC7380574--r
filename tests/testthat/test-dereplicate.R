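mk_pair <- function(ani_qs, ani_sq, cov_q, cov_s) {
  tibble::tibble(query = "a", subject = "b", ani_qs = ani_qs, cov_q = cov_q,
                 ani_sq = ani_sq, cov_s = cov_s)
}

test_that("the both-comparisons rule requires all four thresholds", {
  cfg <- derep_config(ani_threshold = 99, coverage_threshold = 75)
  expect_true(pair_redundant(mk_pair(99.5, 99.4, 90, 88), cfg))
  expect_false(pair_redundant(mk_pair(99.5, 99.5, 90, 60), cfg))
  expect_false(pair_redundant(mk_pair(98.9, 99.2, 90, 90), cfg))
  expect_false(pair_redundant(mk_pair(NA, 99.5, 0, 90), cfg))
  # vectorised over rows
  many <- dplyr::bind_rows(mk_pair(100, 100, 100, 100),
                           mk_pair(99, 99, 75, 75),
                           mk_pair(99, 98.99, 75, 75))
  expect_equal(pair_redundant(many, cfg), c(TRUE, TRUE, FALSE))
})

test_that("secondary clusters form components or complete groups as configured", {
  ids <- c("a", "b", "c")
  pairs <- tibble::tibble(query = c("a", "a", "b"), subject = c("b", "c", "c"),
                          ani_qs = c(99.5, 0, 99.5), ani_sq = c(99.5, 0, 99.5),
                          cov_q = c(90, 0, 90), cov_s = c(90, 0, 90))
  con <- secondary_clusters(ids, pairs, derep_config())
  expect_equal(length(unique(con$secondary_cluster)), 1)

  scores <- c(a = 99, b = 95, c = 90)
  comp <- secondary_clusters(ids, pairs,
                             derep_config(grouping = "complete"), scores)
  expect_equal(comp$secondary_cluster[comp$genome_id %in% c("a", "b")],
               c(1L, 1L))
  expect_equal(comp$secondary_cluster[comp$genome_id == "c"], 2L)

  none <- pairs; none$ani_qs <- 0
  sing <- secondary_clusters(ids, none, derep_config())
  expect_equal(length(unique(sing$secondary_cluster)), 3)

  expect_error(secondary_clusters(c(ids, "d"), pairs, derep_config()),
               "missing ANI result")
})

test_that("representative selection scores completeness against contamination", {
  q <- tibble::tibble(genome_id = c("g1", "g2"),
                      completeness = c(98, 92), contamination = c(2, 0))
  # scores 88 vs 92 at w = 5: the cleaner genome wins
  expect_equal(select_representative(c("g1", "g2"), q), "g2")
  # w = 0: completeness alone
  expect_equal(select_representative(c("g1", "g2"), q,
                                     derep_config(score_weight = 0)), "g1")
  q2 <- tibble::tibble(genome_id = c("g1", "g2", "g3"),
                       completeness = c(100, 90, 100), contamination = 0)
  expect_equal(select_representative(c("g1", "g2"), q2), "g1")
  # ties: larger genome, then lexicographic id
  expect_equal(select_representative(c("g1", "g3"), q2,
                                     total_lengths = c(g1 = 10, g3 = 20)), "g3")
  expect_equal(select_representative(c("g1", "g3"), q2,
                                     total_lengths = c(g1 = 10, g3 = 10)), "g1")
  expect_error(select_representative(c("g1", "nope"), q), "nope")
})

test_that("two identical genomes collapse to the higher-scoring representative", {
  s <- rand_seq(6000, 50)
  g <- dplyr::bind_rows(make_genome("low", s), make_genome("high", s))
  q <- tibble::tibble(genome_id = c("low", "high"),
                      completeness = c(90, 99), contamination = c(0, 0))
  rep <- run_pipeline(g, q)
  expect_equal(sum(rep$clusters$kept), 1)
  expect_equal(rep$clusters$representative[1], "high")
  expect_equal(glance(rep)$n_secondary_clusters, 1)
})

test_that("dereplication is idempotent and one genome is kept per cluster", {
  ms <- local_small_mag_set()
  rep1 <- run_pipeline(ms$genomes, ms$quality)
  expect_equal(sum(rep1$clusters$kept), glance(rep1)$n_secondary_clusters)
  kept <- rep1$clusters$genome_id[rep1$clusters$kept]
  rep2 <- run_pipeline(ms$genomes[ms$genomes$genome_id %in% kept, ],
                       ms$quality[ms$quality$genome_id %in% kept, ])
  expect_setequal(rep2$clusters$genome_id[rep2$clusters$kept], kept)
})

test_that("raising ANI or coverage thresholds never decreases retained genomes", {
  ms <- local_small_mag_set()
  rep <- run_pipeline(ms$genomes, ms$quality)
  pc <- rep$clusters[c("genome_id", "precluster")]
  retained_at <- function(theta, gamma) {
    cfg <- derep_config(ani_threshold = theta, coverage_threshold = gamma)
    sum(vapply(split(pc$genome_id, pc$precluster), function(cl) {
      if (length(cl) < 2) return(1L)
      pr <- rep$pairs[rep$pairs$query %in% cl & rep$pairs$subject %in% cl, ]
      length(unique(secondary_clusters(cl, pr, cfg)$secondary_cluster))
    }, integer(1)))
  }
  thetas <- c(95, 99, 99.9)
  gammas <- c(25, 75, 95)
  grid <- outer(thetas, gammas, Vectorize(retained_at))
  expect_true(all(diff(grid) >= 0))        # theta rises down rows
  expect_true(all(apply(grid, 1, diff) >= 0))  # gamma rises across columns
})
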