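#' Pre-clustering configuration
#'
#' Pre-clusters (Mash clusters) are coarse genome groups cut from a
#' hierarchical clustering of the sketch distance matrix; exact pairwise ANI
#' is computed only within them.
#'
#' @param linkage Agglomeration method: `"average"` (default), `"single"`,
#'   or `"complete"`.
#' @param criterion Flat-cut criterion: `"inconsistent"` (default), which
#'   cuts on the inconsistency coefficient of each merge, or `"distance"`,
#'   which cuts on raw merge height. A raw-distance cut at the default
#'   threshold 2 would be vacuous (Mash distances are at most 1), so the
#'   default threshold is only meaningful under the inconsistency criterion.
#' @param threshold Cut threshold `t` (default 2).
#' @param depth Number of merge levels (inclusive) over which inconsistency
#'   statistics are computed (default 2).
#' @return A list of class `precluster_config`.
#' @export
precluster_config <- function(linkage = c("average", "single", "complete"),
                              criterion = c("inconsistent", "distance"),
                              threshold = 2, depth = 2) {
  linkage <- match.arg(linkage)
  criterion <- match.arg(criterion)
  stopifnot(threshold > 0, depth >= 1)
  structure(list(linkage = linkage, criterion = criterion,
                 threshold = threshold, depth = as.integer(depth)),
            class = "precluster_config")
}

#' Build an agglomerative merge tree from a distance matrix
#'
#' Genomes are sorted lexicographically by id before linkage so the tree is
#' independent of input order; `stats::hclust` performs the agglomeration.
#'
#' @param d Symmetric, zero-diagonal distance matrix with genome ids as
#'   dimnames.
#' @param linkage `"average"`, `"single"`, or `"complete"`.
#' @return A list of class `magderep_dendrogram` wrapping the `hclust`
#'   merge matrix, merge heights, and leaf labels.
#' @export
build_linkage <- function(d, linkage = "average") {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2)
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal is not zero")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(merge = hc$merge, height = hc$height, labels = hc$labels),
            class = "magderep_dendrogram")
}

# Heights of merges within `depth` levels below merge i, inclusive.
merge_height_set <- function(dend, i, depth) {
  if (depth == 0 || i < 0) return(numeric(0))
  kids <- dend$merge[i, ]
  c(dend$height[i],
    if (kids[1] > 0) merge_height_set(dend, kids[1], depth - 1),
    if (kids[2] > 0) merge_height_set(dend, kids[2], depth - 1))
}

#' Inconsistency coefficient of each merge
#'
#' For each merge, the coefficient is `(height - mean) / sd` over the
#' heights of all merges within `depth` levels below it (the merge itself
#' counts as level one); the standard deviation uses the sample (n - 1)
#' denominator. Merges whose height set has zero spread (including
#' leaf-only merges) get coefficient 0. This matches the default criterion
#' of SciPy's flat-cluster extraction.
#'
#' @param dend A `magderep_dendrogram` from [build_linkage()].
#' @param depth Levels included in the statistics (default 2).
#' @return Numeric vector, one coefficient per merge.
#' @export
inconsistency_coefficients <- function(dend, depth = 2) {
  stopifnot(inherits(dend, "magderep_dendrogram"))
  vapply(seq_along(dend$height), function(i) {
    hs <- merge_height_set(dend, i, depth)
    if (length(hs) < 2) return(0)
    s <- stats::sd(hs)
    # guard against floating jitter in tied merge heights
    if (s <= 1e-10 * max(1, abs(dend$height[i]))) return(0)
    (dend$height[i] - mean(hs)) / s
  }, numeric(1))
}

#' Extract flat clusters from a merge tree
#'
#' Cuts the tree so that no merge inside a cluster exceeds the threshold
#' under the chosen criterion: the inconsistency coefficient (default) or
#' the raw merge height (`criterion = "distance"`). Labels are 1-based and
#' numbered by first appearance in `genome_order` (default: the
#' dendrogram's leaf label order).
#'
#' @param dend A `magderep_dendrogram`.
#' @param config A [precluster_config()].
#' @param genome_order Character vector fixing label numbering order.
#' @return A tibble with columns `genome_id`, `precluster`.
#' @export
flat_clusters <- function(dend, config = precluster_config(),
                          genome_order = dend$labels) {
  stopifnot(inherits(dend, "magderep_dendrogram"))
  n <- length(dend$labels)
  crit <- switch(config$criterion,
                 inconsistent = inconsistency_coefficients(dend, config$depth),
                 distance = dend$height)
  nm <- length(dend$height)
  # max criterion value over each merge's subtree (post-order: children of
  # merge i always have smaller index in hclust merge matrices)
  maxcrit <- numeric(nm)
  for (i in seq_len(nm)) {
    kids <- dend$merge[i, ]
    maxcrit[i] <- max(crit[i],
                      if (kids[1] > 0) maxcrit[kids[1]] else -Inf,
                      if (kids[2] > 0) maxcrit[kids[2]] else -Inf)
  }
  # assign leaves: descend from the root; a merge with maxcrit <= t roots a
  # cluster; otherwise recurse, and bare leaves become singletons
  assignment <- integer(n)
  next_label <- 0L
  leaves_of <- function(i) {
    kids <- dend$merge[i, ]
    c(if (kids[1] < 0) -kids[1] else leaves_of(kids[1]),
      if (kids[2] < 0) -kids[2] else leaves_of(kids[2]))
  }
  walk <- function(node) {
    if (node < 0) { # bare leaf -> singleton cluster
      next_label <<- next_label + 1L
      assignment[-node] <<- next_label
    } else if (maxcrit[node] <= config$threshold) {
      next_label <<- next_label + 1L
      assignment[leaves_of(node)] <<- next_label
    } else {
      walk(dend$merge[node, 1])
      walk(dend$merge[node, 2])
    }
  }
  if (nm > 0) walk(nm)
  out <- tibble::tibble(genome_id = dend$labels, precluster = assignment)
  # renumber by first appearance in genome_order
  out <- out[match(genome_order, out$genome_id), , drop = FALSE]
  out$precluster <- as.integer(factor(out$precluster, levels = unique(out$precluster)))
  out
}

#' Pre-cluster genomes from sequences
#'
#' Composition of sketching, Mash distances, linkage, and flat-cluster
#' extraction. A single genome passes through as one singleton cluster.
#'
#' @param genomes A contig table.
#' @param params [sketch_params()].
#' @param config [precluster_config()].
#' @return A tibble with columns `genome_id`, `precluster` (1-based labels
#'   ordered by first genome appearance).
#' @export
precluster <- function(genomes, params = sketch_params(),
                       config = precluster_config()) {
  check_genomes(genomes)
  ids <- unique(genomes$genome_id)
  if (length(ids) == 1) {
    return(tibble::tibble(genome_id = ids, precluster = 1L))
  }
  sk <- sketch_genomes(genomes, params)
  d <- mash_dist_matrix(sk)
  dend <- build_linkage(d, config$linkage)
  flat_clusters(dend, config, genome_order = ids)
}
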