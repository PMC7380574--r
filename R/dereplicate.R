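#' Dereplication configuration
#'
#' @param ani_threshold ANI threshold in percent (default 99): both
#'   directions of a pair must reach it.
#' @param coverage_threshold Alignment-coverage threshold in percent
#'   (default 75): both genomes must be covered to at least this fraction
#'   by accepted alignments of the pair.
#' @param grouping How passing pairs form redundancy groups within a
#'   pre-cluster: `"connected"` (default) takes connected components of the
#'   pass graph; `"complete"` builds maximal groups in which every pair
#'   passes, greedily from the highest-quality seed.
#' @param score_weight Contamination multiplier `w` in the representative
#'   score `completeness - w * contamination` (default 5; `w = 0` selects
#'   purely on completeness).
#' @return A list of class `derep_config`.
#' @export
derep_config <- function(ani_threshold = 99, coverage_threshold = 75,
                         grouping = c("connected", "complete"),
                         score_weight = 5) {
  grouping <- match.arg(grouping)
  stopifnot(ani_threshold > 0, ani_threshold <= 100,
            coverage_threshold > 0, coverage_threshold <= 100,
            score_weight >= 0)
  structure(list(ani_threshold = ani_threshold,
                 coverage_threshold = coverage_threshold,
                 grouping = grouping, score_weight = score_weight),
            class = "derep_config")
}

#' Decide whether an ANI result makes a pair redundant
#'
#' A pair is redundant only when it meets the thresholds with both
#' comparisons: ANI at or above the threshold in both directions AND
#' coverage at or above the threshold for both genomes. Pairs with an
#' undefined ANI (no accepted fragments) are never redundant.
#'
#' @param pairs An ANI result table from [pairwise_ani()] (vectorised over
#'   rows).
#' @param config A [derep_config()].
#' @return Logical vector, one decision per row.
#' @export
pair_redundant <- function(pairs, config = derep_config()) {
  th <- config$ani_threshold
  gm <- config$coverage_threshold
  ok <- !is.na(pairs$ani_qs) & !is.na(pairs$ani_sq) &
    pairs$ani_qs >= th & pairs$ani_sq >= th &
    pairs$cov_q >= gm & pairs$cov_s >= gm
  unname(ok)
}

#' Group genomes of a pre-cluster into secondary clusters
#'
#' @param ids Genome ids of the pre-cluster.
#' @param pairs ANI results covering every unordered pair of `ids`.
#' @param config A [derep_config()].
#' @param scores Named numeric vector of quality scores (required for
#'   `grouping = "complete"`, where groups grow greedily from the
#'   highest-scoring seed).
#' @return A tibble with columns `genome_id`, `secondary_cluster` (1-based,
#'   ordered by first appearance in `ids`).
#' @export
secondary_clusters <- function(ids, pairs, config = derep_config(),
                               scores = NULL) {
  if (length(ids) > 1) {
    want <- utils::combn(sort(ids), 2)
    have <- paste(pairs$query, pairs$subject)
    missing <- !(paste(want[1, ], want[2, ]) %in% have)
    if (any(missing)) {
      stop("missing ANI result for pair ", want[1, which(missing)[1]], " vs ",
           want[2, which(missing)[1]])
    }
  }
  pass <- pairs[pair_redundant(pairs, config), c("query", "subject"), drop = FALSE]
  membership <- switch(config$grouping,
    connected = {
      g <- igraph::graph_from_data_frame(pass, directed = FALSE,
                                         vertices = data.frame(name = ids))
      igraph::components(g)$membership[ids]
    },
    complete = {
      if (is.null(scores)) stop("grouping = 'complete' needs quality scores")
      edge <- matrix(FALSE, length(ids), length(ids),
                     dimnames = list(ids, ids))
      if (nrow(pass) > 0) {
        edge[cbind(pass$query, pass$subject)] <- TRUE
        edge[cbind(pass$subject, pass$query)] <- TRUE
      }
      memb <- setNames(rep(NA_integer_, length(ids)), ids)
      lab <- 0L
      pool <- ids[order(-scores[ids], ids)]
      while (length(pool) > 0) {
        lab <- lab + 1L
        group <- pool[1]
        for (cand in pool[-1]) {
          if (all(edge[cand, group])) group <- c(group, cand)
        }
        memb[group] <- lab
        pool <- setdiff(pool, group)
      }
      memb[ids]
    })
  out <- tibble::tibble(genome_id = ids, secondary_cluster = membership)
  out$secondary_cluster <-
    as.integer(factor(out$secondary_cluster, levels = unique(out$secondary_cluster)))
  out
}

#' Select the representative genome of a redundancy group
#'
#' The representative maximises `completeness - w * contamination`; ties
#' break by larger total genome length, then lexicographic id.
#'
#' @param ids Genome ids of the group.
#' @param quality Quality table covering every id.
#' @param config A [derep_config()].
#' @param total_lengths Named numeric vector of genome lengths (used only
#'   for tie-breaking; defaults to zeros).
#' @return The representative genome id.
#' @export
select_representative <- function(ids, quality, config = derep_config(),
                                  total_lengths = NULL) {
  q <- quality[match(ids, quality$genome_id), ]
  if (anyNA(q$genome_id)) {
    stop("missing quality row for genome ", ids[which(is.na(q$genome_id))[1]])
  }
  score <- q$completeness - config$score_weight * q$contamination
  len <- if (is.null(total_lengths)) rep(0, length(ids)) else total_lengths[ids]
  ids[order(-score, -len, ids)][1]
}

new_derep_report <- function(clusters, pairs, configs = list()) {
  structure(list(clusters = clusters, pairs = pairs, configs = configs),
            class = "derep_report")
}

#' @export
print.derep_report <- function(x, ...) {
  g <- glance(x)
  cat("Dereplication report: ", g$n_genomes, " genomes -> ",
      g$n_retained, " representatives (",
      g$n_preclusters, " pre-clusters, ", g$n_secondary_clusters,
      " secondary clusters)\n", sep = "")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `derep_report`.
#' @param ... Unused.
#' @method tidy derep_report
#' @export
tidy.derep_report <- function(x, ...) x$clusters

#' @rdname run_pipeline
#' @method glance derep_report
#' @export
glance.derep_report <- function(x, ...) {
  tibble::tibble(n_genomes = nrow(x$clusters),
                 n_preclusters = length(unique(x$clusters$precluster)),
                 n_secondary_clusters =
                   nrow(unique(x$clusters[c("precluster", "secondary_cluster")])),
                 n_retained = sum(x$clusters$kept))
}

#' @rdname run_pipeline
#' @method autoplot derep_report
#' @export
autoplot.derep_report <- function(object, ...) {
  dat <- object$clusters |>
    dplyr::count(.data$precluster, .data$secondary_cluster, .data$kept)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = interaction(.data$precluster, .data$secondary_cluster, sep = "."),
    y = .data$n, fill = .data$kept)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "pre-cluster.secondary-cluster", y = "genomes",
                  fill = "kept") +
    ggplot2::theme_minimal()
}

#' Dereplicate a genome set end to end
#'
#' Reads genomes (or takes a contig table), sketches them, pre-clusters by
#' Mash distance, computes bidirectional fragment ANI within each
#' pre-cluster, groups redundant genomes, and selects one representative per
#' group by quality score. All stages are deterministic given the inputs, so
#' repeated runs produce identical reports.
#'
#' @param genomes A contig table or a directory of FASTA files.
#' @param quality A quality table or path to one (`genome_id`,
#'   `completeness`, `contamination`).
#' @param sketch [sketch_params()].
#' @param pre [precluster_config()].
#' @param ani [ani_config()].
#' @param derep [derep_config()].
#' @return A `derep_report`: `clusters` (per-genome assignment and kept
#'   flag), `pairs` (within-pre-cluster ANI results with pass decisions),
#'   and the configurations used. Methods: [tidy()], [glance()],
#'   [ggplot2::autoplot()].
#' @export
run_pipeline <- function(genomes, quality,
                         sketch = sketch_params(),
                         pre = precluster_config(),
                         ani = ani_config(),
                         derep = derep_config()) {
  if (is.character(genomes)) genomes <- read_genome_dir(genomes)
  if (is.character(quality)) quality <- read_quality_table(quality)
  check_genomes(genomes)
  ids <- unique(genomes$genome_id)
  miss_q <- setdiff(ids, quality$genome_id)
  if (length(miss_q) > 0) {
    stop("missing quality row for genome(s): ", paste(miss_q, collapse = ", "))
  }

  pc <- precluster(genomes, sketch, pre)
  lens <- genome_stats(genomes)
  total_lengths <- setNames(lens$total_length, lens$genome_id)
  scores <- setNames(quality$completeness -
                       derep$score_weight * quality$contamination,
                     quality$genome_id)

  all_pairs <- list()
  assign <- list()
  for (cl in sort(unique(pc$precluster))) {
    cl_ids <- pc$genome_id[pc$precluster == cl]
    if (length(cl_ids) < 2) {
      assign[[length(assign) + 1]] <-
        tibble::tibble(genome_id = cl_ids, precluster = cl,
                       secondary_cluster = 1L)
      next
    }
    pr <- pairwise_ani(genomes[genomes$genome_id %in% cl_ids, ], ani,
                       ids = cl_ids)
    all_pairs[[length(all_pairs) + 1]] <- pr
    sc <- secondary_clusters(cl_ids, pr, derep, scores = scores)
    sc$precluster <- cl
    assign[[length(assign) + 1]] <- sc[c("genome_id", "precluster",
                                         "secondary_cluster")]
  }
  clusters <- dplyr::bind_rows(assign)

  reps <- clusters |>
    dplyr::group_by(.data$precluster, .data$secondary_cluster) |>
    dplyr::summarise(representative = select_representative(
      .data$genome_id, quality, derep, total_lengths), .groups = "drop")
  clusters <- clusters |>
    dplyr::left_join(reps, by = c("precluster", "secondary_cluster")) |>
    dplyr::mutate(kept = .data$genome_id == .data$representative,
                  score = unname(scores[.data$genome_id]))
  clusters <- clusters[match(ids, clusters$genome_id), , drop = FALSE]

  pairs <- if (length(all_pairs) > 0) dplyr::bind_rows(all_pairs) else
    tibble::tibble(query = character(), subject = character(),
                   ani_qs = numeric(), cov_q = numeric(),
                   ani_sq = numeric(), cov_s = numeric(),
                   n_fragments_q = integer(), n_fragments_s = integer(),
                   accepted_q = integer(), accepted_s = integer())
  if (nrow(pairs) > 0) pairs$pass <- pair_redundant(pairs, derep)

  new_derep_report(clusters = tibble::as_tibble(clusters), pairs = pairs,
                   configs = list(sketch = sketch, pre = pre, ani = ani,
                                  derep = derep))
}
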