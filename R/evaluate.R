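#' Artificially reduce a genome's completeness by subsampling contigs
#'
#' Contigs are shuffled with a seeded generator and the longest prefix whose
#' cumulative length stays within `fraction` of the total is retained —
#' never fewer than one contig. Retained contigs keep their original order
#' and sequences.
#'
#' @param genomes A contig table (all genomes are subsampled independently).
#' @param fraction Target completeness fraction in (0, 1\].
#' @param seed Integer seed.
#' @return A contig table with the retained contigs.
#' @export
subsample_to_completeness <- function(genomes, fraction, seed = 1) {
  check_genomes(genomes)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  withr::with_seed(seed, {
    genomes |>
      dplyr::group_by(.data$genome_id) |>
      dplyr::group_modify(function(g, key) {
        ord <- sample.int(nrow(g))
        lens <- nchar(g$sequence[ord])
        keep_n <- max(1L, sum(cumsum(lens) <= fraction * sum(nchar(g$sequence))))
        keep <- sort(ord[seq_len(keep_n)])
        g[keep, , drop = FALSE]
      }) |>
      dplyr::ungroup()
  })
}

#' Retained-genome counts across a completeness-by-coverage grid
#'
#' For each completeness fraction, every genome is subsampled and the full
#' pipeline run; for each coverage threshold the number of retained
#' representatives is recorded. ANI results are computed once per
#' subsampled set and re-thresholded per coverage value, which is
#' equivalent to re-running the pipeline cell by cell.
#'
#' @param genomes A contig table (at least 2 genomes).
#' @param quality Quality table covering all genomes.
#' @param fractions Completeness fractions to test (default 0.1 to 1 by 0.1).
#' @param coverage_thresholds Coverage thresholds in percent
#'   (default 10, 25, 50, 75).
#' @param replicates Independent subsampling replicates per fraction
#'   (default 1).
#' @param seed Integer master seed.
#' @param sketch,pre,ani,derep Stage configurations as in [run_pipeline()].
#' @return A tibble of class `completeness_grid` with columns `fraction`,
#'   `coverage_threshold`, `replicate`, `retained`.
#' @export
completeness_experiment <- function(genomes, quality,
                                    fractions = seq(0.1, 1, by = 0.1),
                                    coverage_thresholds = c(10, 25, 50, 75),
                                    replicates = 1, seed = 1,
                                    sketch = sketch_params(),
                                    pre = precluster_config(),
                                    ani = ani_config(),
                                    derep = derep_config()) {
  check_genomes(genomes)
  stopifnot(all(fractions > 0 & fractions <= 1),
            all(coverage_thresholds > 0 & coverage_thresholds <= 100))
  if (length(unique(genomes$genome_id)) < 2) stop("need at least 2 genomes")
  scores <- setNames(quality$completeness -
                       derep$score_weight * quality$contamination,
                     quality$genome_id)
  cells <- tidyr::expand_grid(replicate = seq_len(replicates),
                              fraction = fractions)
  out <- purrr::pmap(cells, function(replicate, fraction) {
    sub_seed <- (seed + 7919L * replicate +
                   round(1000 * fraction)) %% .Machine$integer.max
    sub <- subsample_to_completeness(genomes, fraction, seed = sub_seed)
    pc <- precluster(sub, sketch, pre)
    cluster_ids <- split(pc$genome_id, pc$precluster)
    cluster_pairs <- lapply(cluster_ids, function(cl) {
      if (length(cl) < 2) return(NULL)
      pairwise_ani(sub[sub$genome_id %in% cl, ], ani, ids = cl)
    })
    purrr::map(coverage_thresholds, function(gm) {
      cfg <- derep_config(ani_threshold = derep$ani_threshold,
                          coverage_threshold = gm,
                          grouping = derep$grouping,
                          score_weight = derep$score_weight)
      retained <- sum(vapply(seq_along(cluster_ids), function(i) {
        cl <- cluster_ids[[i]]
        if (length(cl) < 2) return(1L)
        sc <- secondary_clusters(cl, cluster_pairs[[i]], cfg, scores = scores)
        length(unique(sc$secondary_cluster))
      }, integer(1)))
      tibble::tibble(fraction = fraction, coverage_threshold = gm,
                     replicate = replicate, retained = retained)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(out) <- c("completeness_grid", class(out))
  out
}

#' @rdname completeness_experiment
#' @param object A `completeness_grid`.
#' @param ... Unused.
#' @method autoplot completeness_grid
#' @export
autoplot.completeness_grid <- function(object, ...) {
  dat <- object |>
    dplyr::group_by(.data$fraction, .data$coverage_threshold) |>
    dplyr::summarise(retained = mean(.data$retained), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(100 * .data$fraction),
                                    y = factor(.data$coverage_threshold),
                                    fill = .data$retained)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$retained, 1)),
                       colour = "white") +
    ggplot2::labs(x = "genome completeness (%)",
                  y = "coverage threshold (%)", fill = "retained") +
    ggplot2::theme_minimal()
}

#' Gene-cluster retention after dereplication
#'
#' Counts how many pangenome gene clusters keep at least one representative
#' among the retained genomes.
#'
#' @param table A gene-cluster membership table (`genome_id`, `cluster_id`).
#' @param kept Character vector of retained genome ids (must all appear in
#'   the table).
#' @return A one-row tibble with `universe`, `retained`, `lost`, and a
#'   list-column `lost_ids` naming the lost clusters;
#'   `retained + lost = universe` always.
#' @export
gene_cluster_retention <- function(table, kept) {
  stopifnot(all(c("genome_id", "cluster_id") %in% names(table)))
  missing <- setdiff(kept, table$genome_id)
  if (length(missing) > 0) {
    stop("kept genome absent from gene-cluster table: ",
         paste(missing, collapse = ", "))
  }
  universe <- unique(table$cluster_id)
  kept_clusters <- unique(table$cluster_id[table$genome_id %in% kept])
  lost_ids <- setdiff(universe, kept_clusters)
  tibble::tibble(universe = length(universe),
                 retained = length(kept_clusters),
                 lost = length(lost_ids),
                 lost_ids = list(lost_ids))
}

#' Simulate read-coverage dilution across a redundant genome database
#'
#' Draws reads uniformly from a source genome and assigns each read to the
#' database genome(s) containing its best match. For identical redundant
#' genomes an exact-substring search (both strands) suffices; reads without
#' an exact hit fall back to the fragment aligner. Ties are broken uniformly
#' at random with the seeded generator (emulating a mapper reporting one
#' random alignment among equals); `report_all = TRUE` instead credits every
#' tied genome.
#'
#' @param db A contig table: the genome database reads are mapped against.
#' @param source Genome id the reads are drawn from (must be in `db`'s id
#'   universe or supplied via `source_genomes`).
#' @param n_reads Number of reads.
#' @param read_length Read length in bp (at most the shortest source
#'   contig).
#' @param seed Integer seed.
#' @param source_genomes Optional contig table to draw reads from when the
#'   source is not part of `db`.
#' @param report_all Credit all tied genomes instead of one at random.
#' @return A tibble of class `dilution_result` with `genome_id`, `reads`,
#'   `mean_coverage` (= reads * read_length / genome length).
#' @export
coverage_dilution_sim <- function(db, source, n_reads = 4000,
                                  read_length = 150, seed = 1,
                                  source_genomes = NULL,
                                  report_all = FALSE) {
  check_genomes(db)
  src <- if (is.null(source_genomes)) db[db$genome_id == source, ] else
    source_genomes[source_genomes$genome_id == source, ]
  if (nrow(src) == 0) stop("source genome not found: ", source)
  if (read_length > min(nchar(src$sequence))) {
    stop("read length exceeds the shortest source contig")
  }
  ids <- unique(db$genome_id)

  withr::with_seed(seed, {
    n_pos <- nchar(src$sequence) - read_length + 1L
    contig_idx <- sample.int(nrow(src), n_reads, replace = TRUE,
                             prob = n_pos / sum(n_pos))
    pos <- floor(runif(n_reads) * n_pos[contig_idx]) + 1L
    reads <- substring(src$sequence[contig_idx], pos, pos + read_length - 1L)
    strand <- runif(n_reads) < 0.5
    reads_dna <- Biostrings::DNAStringSet(reads)
    reads_dna[strand] <- Biostrings::reverseComplement(reads_dna[strand])

    pd_fwd <- Biostrings::PDict(reads_dna)
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(reads_dna))
    member <- matrix(FALSE, n_reads, length(ids), dimnames = list(NULL, ids))
    for (g in ids) {
      subj <- Biostrings::DNAStringSet(db$sequence[db$genome_id == g])
      cnt <- rowSums(Biostrings::vcountPDict(pd_fwd, subj)) +
        rowSums(Biostrings::vcountPDict(pd_rev, subj))
      member[, g] <- cnt > 0
    }

    # fallback: best-identity alignment for reads with no exact hit anywhere
    no_hit <- which(rowSums(member) == 0)
    cfg <- ani_config(fragment_length = max(read_length, 101L),
                      min_fragment = min(read_length, 100L))
    for (r in no_hit) {
      best <- -Inf; best_g <- character(0)
      for (g in ids) {
        res <- one_way_ani_cpp(as.character(reads_dna[r]),
                               db$sequence[db$genome_id == g],
                               cfg$seed_k,
                               as.integer(cfg$band_fraction * read_length),
                               cfg$min_hit_identity, cfg$min_hit_fraction)
        if (isTRUE(res$hit) && res$identity > best) {
          best <- res$identity; best_g <- g
        } else if (isTRUE(res$hit) && res$identity == best) {
          best_g <- c(best_g, g)
        }
      }
      member[r, best_g] <- TRUE
    }

    counts <- setNames(numeric(length(ids)), ids)
    unplaced <- 0L
    for (r in seq_len(n_reads)) {
      hits <- ids[member[r, ]]
      if (length(hits) == 0) { unplaced <- unplaced + 1L; next }
      if (report_all) {
        counts[hits] <- counts[hits] + 1
      } else {
        pick <- if (length(hits) == 1) hits else sample(hits, 1)
        counts[pick] <- counts[pick] + 1
      }
    }
    if (unplaced > 0) {
      warning(unplaced, " read(s) could not be placed on any database genome")
    }

    lens <- genome_stats(db)
    out <- tibble::tibble(genome_id = ids,
                          reads = as.integer(unname(counts[ids])),
                          mean_coverage = unname(counts[ids]) * read_length /
                            lens$total_length[match(ids, lens$genome_id)])
    class(out) <- c("dilution_result", class(out))
    out
  })
}

#' @rdname coverage_dilution_sim
#' @param object A `dilution_result`.
#' @param ... Unused.
#' @method autoplot dilution_result
#' @export
autoplot.dilution_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$genome_id,
                                       y = .data$mean_coverage)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean read coverage (x)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
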