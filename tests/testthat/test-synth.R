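test_that("ancestors are deterministic per seed with near-uniform composition", {
  expect_equal(generate_ancestor(2000, seed = 4), generate_ancestor(2000, seed = 4))
  a <- generate_ancestor(200000, seed = 8)
  gc <- sum(strsplit(a, "")[[1]] %in% c("G", "C")) / 200000
  expect_lt(abs(gc - 0.5), 0.01)
  # unrelated seeds share essentially no 21-mers
  b <- generate_ancestor(20000, seed = 9)
  a_short <- substr(a, 1, 20000)
  expect_lt(oracle_jaccard(a_short, b, 21), 0.001)
})

test_that("evolution places the prescribed substitution load and replays exactly", {
  anc <- generate_ancestor(200000, seed = 14)
  idle <- evolve_sequence(anc, 100, indel_rate = 0, seed = 1)
  expect_equal(idle$sequence, anc)
  expect_equal(nrow(idle$mask), 0)

  ev <- evolve_sequence(anc, 99, indel_rate = 0, seed = 2)
  expect_lt(abs(nrow(ev$mask) - 2000), 3 * sqrt(2000))
  expect_true(all(ev$mask$type == "sub"))
  expect_true(all(ev$mask$ref != ev$mask$alt))
  expect_equal(apply_mutation_mask(anc, ev$mask), ev$sequence)

  withind <- evolve_sequence(anc, 99.5, indel_rate = 5e-4, seed = 3)
  expect_equal(apply_mutation_mask(anc, withind$mask), withind$sequence)
  expect_true(all(c("sub", "ins", "del") %in% withind$mask$type))
})

test_that("generated MAG sets carry consistent truth and bookkeeping", {
  ms <- local_small_mag_set()
  cfg <- ms$config
  ids <- unique(ms$genomes$genome_id)
  expect_length(ids, cfg$n_species * cfg$mags_per_species)
  expect_setequal(ms$truth$genome_id, ids)
  expect_setequal(ms$quality$genome_id, ids)
  # species labels partition the set evenly
  expect_equal(as.integer(table(ms$truth$species)),
               rep(cfg$mags_per_species, cfg$n_species))
  # gene-cluster universe: one core per species plus the planted aux pool
  expect_equal(length(unique(ms$gene_clusters$cluster_id)),
               cfg$n_species * (1 + cfg$aux_blocks_per_genome))
  # every MAG is in its species core cluster
  core <- ms$gene_clusters[grepl("_core$", ms$gene_clusters$cluster_id), ]
  expect_setequal(core$genome_id, ids)
  # complete genomes: quality close to 100, contamination zero
  expect_true(all(ms$quality$completeness > 97))
  expect_true(all(ms$quality$contamination == 0))
  expect_equal(nrow(dplyr::count(ms$genomes, genome_id)),
               length(ids))
  expect_true(all(dplyr::count(ms$genomes, genome_id)$n == cfg$n_contigs))
})

test_that("single-MAG sets are trivially complete", {
  ms <- generate_mag_set(synth_config(n_species = 1, mags_per_species = 1,
                                      genome_length = 30000, n_contigs = 5,
                                      seed = 3))
  expect_equal(nrow(ms$truth), 1)
  expect_gt(ms$quality$completeness, 97)
})

test_that("measured ANI between generated genomes matches the configured targets", {
  # substitution-only mode: conspecific pairs land on the pairwise target
  ms <- generate_mag_set(synth_config(n_species = 2, mags_per_species = 2,
                                      genome_length = 60000, n_contigs = 10,
                                      within_ani = 99.5, between_ani = 80,
                                      indel_rate = 0, aux_blocks_per_genome = 0,
                                      seed = 21))
  g <- ms$genomes
  within <- pairwise_ani(g, ids = c("sp01_mag01", "sp01_mag02"))
  expect_lt(abs(within$ani_qs - 99.5), 0.3)
  expect_lt(abs(within$ani_sq - 99.5), 0.3)
  between <- pairwise_ani(g, ids = c("sp01_mag01", "sp02_mag01"))
  ani_b <- c(between$ani_qs, between$ani_sq)
  ani_b <- ani_b[!is.na(ani_b)]
  # independent ancestors: any chance alignments sit far below species level
  if (length(ani_b) > 0) expect_true(all(ani_b <= 85))
})

test_that("MAG sets round-trip through disk in CLI formats", {
  ms <- local_small_mag_set()
  dir <- withr::local_tempdir()
  write_mag_set(ms, dir)
  g <- read_genome_dir(dir)
  expect_equal(g, ms$genomes)
  q <- read_quality_table(file.path(dir, "quality.tsv"))
  expect_equal(q, ms$quality)
  gc <- read_gene_cluster_table(file.path(dir, "gene_clusters.tsv"))
  expect_equal(dplyr::arrange(gc, genome_id, cluster_id),
               dplyr::arrange(ms$gene_clusters, genome_id, cluster_id))
})
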