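test_that("sketches are invariant under reverse complement and contig order", {
  seqs <- c(rand_seq(4000, 1), rand_seq(3000, 2))
  g <- make_genome("g", seqs)
  g_rc <- make_genome("g", revcomp_chr(seqs))
  g_perm <- make_genome("g", rev(seqs))
  p <- sketch_params(s = 500)
  expect_equal(sketch_genomes(g, p)$hashes, sketch_genomes(g_rc, p)$hashes)
  expect_equal(sketch_genomes(g, p)$hashes, sketch_genomes(g_perm, p)$hashes)
  # determinism across calls
  expect_equal(sketch_genomes(g, p)$hashes, sketch_genomes(g, p)$hashes)
})

test_that("sketch size equals the brute-force count of distinct canonical k-mers", {
  # oracle: enumerate all k-mer windows, canonicalise each against its
  # reverse complement, deduplicate
  for (sd in c(9, 19)) {
    s2 <- rand_seq(40, sd)
    win <- substring(s2, 1:30, 11:40)
    n_canon <- length(unique(pmin(win, revcomp_chr(win))))
    sk2 <- sketch_genomes(make_genome("h", s2), sketch_params(k = 11, s = 100))
    expect_equal(length(sk2$hashes[[1]]), n_canon)
  }
})

test_that("k-mers containing N are skipped and short genomes error", {
  g <- make_genome("g", paste0(rand_seq(100, 1), "N", rand_seq(100, 2)))
  plain <- dplyr::bind_rows(make_genome("a", substr(g$sequence, 1, 100)),
                            make_genome("b", substr(g$sequence, 102, 201)))
  sk_split <- sketch_genomes(plain, sketch_params(s = 1000))
  sk_n <- sketch_genomes(g, sketch_params(s = 1000))
  expect_setequal(sk_n$hashes[[1]],
                  sort(unique(c(sk_split$hashes[[1]], sk_split$hashes[[2]]))))
  expect_error(sketch_genomes(make_genome("tiny", "ACGTACGT"), sketch_params()),
               "too short")
})

test_that("jaccard estimates and mash distance behave at the extremes", {
  g <- make_genome("g", rand_seq(5000, 7))
  sk <- sketch_genomes(g, sketch_params(s = 200))$hashes[[1]]
  expect_equal(jaccard_estimate(sk, sk, 200), 1)
  expect_equal(jaccard_estimate(sprintf("%016x", 1:50),
                                sprintf("%016x", 1001:1050), 200), 0)
  expect_equal(mash_distance(1, 21), 0)
  expect_equal(mash_distance(0, 21), 1)
  expect_equal(mash_distance(0.5, 21), log(1.5) / 21, tolerance = 1e-12)
  expect_error(mash_distance(1.2), "outside")
})

test_that("sketch Jaccard tracks the exact k-mer Jaccard of half-shared genomes", {
  shared <- rand_seq(50000, 100)
  a <- c(shared, rand_seq(50000, 101))
  b <- c(shared, rand_seq(50000, 102))
  j_exact <- oracle_jaccard(a, b, 21)
  ga <- make_genome("a", a); gb <- make_genome("b", b)
  sk <- sketch_genomes(dplyr::bind_rows(ga, gb), sketch_params())
  j_est <- jaccard_estimate(sk$hashes[[1]], sk$hashes[[2]], 1000)
  expect_lt(abs(j_est - j_exact), 3 * sqrt(j_exact * (1 - j_exact) / 1000))
  # and the C++ exact-Jaccard diagnostic agrees with the string oracle
  expect_equal(exact_kmer_jaccard(dplyr::bind_rows(ga, gb), "a", "b", 21),
               j_exact, tolerance = 1e-10)
})

test_that("distance matrices are symmetric, zero-diagonal, and separate unrelated genomes", {
  g <- dplyr::bind_rows(make_genome("a", rand_seq(100000, 1)),
                        make_genome("b", rand_seq(100000, 2)),
                        make_genome("a2", rand_seq(100000, 1)))
  d <- mash_dist_matrix(sketch_genomes(g))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_gte(d["a", "b"], 0.3)
  expect_equal(d["a", "a2"], 0)
})

test_that("estimated distance grows with the mutated fraction of a genome", {
  anc <- rand_seq(100000, 55)
  for (sd in 1:3) {
    dists <- vapply(c(99.5, 97, 92), function(ani) {
      mut <- evolve_sequence(anc, ani, seed = sd * 100 + ani)$sequence
      g <- dplyr::bind_rows(make_genome("anc", anc), make_genome("mut", mut))
      sk <- sketch_genomes(g)
      mash_dist_matrix(sk)["anc", "mut"]
    }, numeric(1))
    expect_true(all(diff(dists) > 0))
  }
})
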