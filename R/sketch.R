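#' MinHash sketch parameters
#'
#' @param k K-mer length (odd, between 11 and 31). Default 21, the Mash
#'   default.
#' @param s Sketch size: the number of smallest hash values retained.
#'   Default 1000, the Mash default.
#' @param hash_seed Fixed integer seed of the 64-bit k-mer hash. The hash is
#'   a documented splitmix64 mix of the 2-bit-packed canonical k-mer, so
#'   sketches are identical across runs and machines.
#' @return A list of class `sketch_params`.
#' @export
sketch_params <- function(k = 21, s = 1000, hash_seed = 42) {
  stopifnot(k %% 2 == 1, k >= 11, k <= 31, s >= 1)
  structure(list(k = as.integer(k), s = as.integer(s),
                 hash_seed = as.numeric(hash_seed)),
            class = "sketch_params")
}

#' Sketch genomes with bottom-s MinHash over canonical k-mers
#'
#' A sketch is the `s` smallest distinct 64-bit hash values over all
#' canonical k-mers of a genome (the lexicographic minimum of each k-mer and
#' its reverse complement). K-mers containing `N` are skipped. Sketches are
#' invariant under contig reordering and reverse complementation and
#' deterministic given the sequence and parameters.
#'
#' @param genomes A contig table (see [read_genome_dir()]).
#' @param params A [sketch_params()] object.
#' @return A tibble with columns `genome_id`, `k`, `s`, and a list-column
#'   `hashes` of sorted 16-digit hexadecimal hash strings.
#' @export
sketch_genomes <- function(genomes, params = sketch_params()) {
  check_genomes(genomes)
  stopifnot(inherits(params, "sketch_params"))
  genomes |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(hashes = {
      if (max(nchar(.data$sequence)) < params$k) {
        stop("genome too short to sketch: ", dplyr::cur_group()$genome_id,
             " has no contig of length >= k = ", params$k)
      }
      list(sketch_hashes_cpp(.data$sequence, params$k, params$s,
                             params$hash_seed))
    }, .groups = "drop") |>
    dplyr::mutate(k = params$k, s = params$s, .after = "genome_id")
}

#' MinHash Jaccard estimate from two sketches
#'
#' Uses the Mash convention: the merged bottom-s' set, where
#' `s' = min(s, |union of retained hashes|)`; the estimate is the fraction
#' of the s' smallest union hashes present in both sketches. This is the
#' unbiased bottom-sketch estimator of the Jaccard index of the two
#' genomes' canonical k-mer sets.
#'
#' @param a,b Sorted hash vectors (hex strings) from [sketch_genomes()].
#' @param s Sketch size both sketches were built with.
#' @return The estimated Jaccard index in \[0, 1\].
#' @export
jaccard_estimate <- function(a, b, s) {
  u <- sort(unique(c(a, b)))
  sp <- min(s, length(u))
  if (sp == 0) return(0)
  u <- u[seq_len(sp)]
  sum(u %in% a & u %in% b) / sp
}

#' Mash distance from a Jaccard estimate
#'
#' `d = min(1, -(1/k) * log(2j / (1 + j)))`, the Poisson-model conversion of
#' k-mer Jaccard similarity to a per-base mutation distance; `j = 0` maps to
#' the maximal distance 1.
#'
#' @param j Jaccard estimate in \[0, 1\].
#' @param k K-mer length used for sketching.
#' @return Distance in \[0, 1\].
#' @export
mash_distance <- function(j, k = 21) {
  if (any(j < 0 | j > 1)) stop("Jaccard estimate outside [0, 1]")
  d <- ifelse(j <= 0, 1, pmin(1, -(1 / k) * log(2 * j / (1 + j))))
  as.numeric(d)
}

#' Pairwise Mash distance matrix for a set of sketches
#'
#' @param sketches A sketch table from [sketch_genomes()] with at least two
#'   rows; all sketches must share parameters.
#' @return A symmetric, zero-diagonal numeric matrix with genome ids as
#'   dimnames, rows in the input order of `sketches`.
#' @export
mash_dist_matrix <- function(sketches) {
  stopifnot(is.data.frame(sketches),
            all(c("genome_id", "k", "s", "hashes") %in% names(sketches)))
  if (nrow(sketches) < 2) stop("need at least 2 sketches")
  if (length(unique(sketches$k)) != 1 || length(unique(sketches$s)) != 1) {
    stop("sketch parameter mismatch across genomes")
  }
  n <- nrow(sketches)
  k <- sketches$k[1]
  s <- sketches$s[1]
  m <- matrix(0, n, n, dimnames = list(sketches$genome_id, sketches$genome_id))
  for (i in seq_len(n - 1)) {
    for (jdx in seq(i + 1, n)) {
      j <- jaccard_estimate(sketches$hashes[[i]], sketches$hashes[[jdx]], s)
      m[i, jdx] <- m[jdx, i] <- mash_distance(j, k)
    }
  }
  m
}

#' Exact Jaccard index of two genomes' canonical k-mer sets
#'
#' Brute-force set intersection over all distinct canonical k-mers; the
#' quantity that [jaccard_estimate()] approximates from sketches.
#'
#' @param genomes A contig table containing both genomes.
#' @param id_a,id_b Genome ids to compare.
#' @param k K-mer length.
#' @return The exact Jaccard index.
#' @export
exact_kmer_jaccard <- function(genomes, id_a, id_b, k = 21) {
  check_genomes(genomes)
  a <- genomes$sequence[genomes$genome_id == id_a]
  b <- genomes$sequence[genomes$genome_id == id_b]
  if (length(a) == 0 || length(b) == 0) stop("genome id not found")
  exact_kmer_jaccard_cpp(a, b, as.integer(k), 42)
}
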