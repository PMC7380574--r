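#' Fragment-ANI configuration
#'
#' Parameters of the fragment-based, alignment-backed ANI calculation.
#' Genomes are cut into consecutive windows of `fragment_length` bp, each
#' aligned to the other genome by seed-and-extend with a banded alignment;
#' ANI is the mean identity of accepted fragments and coverage the aligned
#' fraction of the genome.
#'
#' @param fragment_length Window length in bp (default 1020, the
#'   BLAST-based genome-ANI convention).
#' @param min_fragment Minimum trailing-window length retained (default 100 bp).
#' @param seed_k Exact seed k-mer length for candidate locus finding
#'   (default 15 bp).
#' @param band_fraction Band width of the alignment as a fraction of
#'   `fragment_length` (default 0.2); caps the detectable indel offset per
#'   fragment.
#' @param min_hit_identity Minimum identity for a fragment hit to be
#'   accepted (default 0.3).
#' @param min_hit_fraction Minimum fraction of the fragment aligned
#'   (default 0.7).
#' @return A list of class `ani_config`.
#' @export
ani_config <- function(fragment_length = 1020, min_fragment = 100,
                       seed_k = 15, band_fraction = 0.2,
                       min_hit_identity = 0.3, min_hit_fraction = 0.7) {
  stopifnot(min_hit_identity > 0, min_hit_identity <= 1,
            min_hit_fraction > 0, min_hit_fraction <= 1,
            seed_k < min_fragment, min_fragment <= fragment_length)
  structure(list(fragment_length = as.integer(fragment_length),
                 min_fragment = as.integer(min_fragment),
                 seed_k = as.integer(seed_k),
                 band_fraction = band_fraction,
                 min_hit_identity = min_hit_identity,
                 min_hit_fraction = min_hit_fraction),
            class = "ani_config")
}

#' Cut a genome into consecutive fragments
#'
#' Each contig is split into windows of `fragment_length` bp; a trailing
#' window is kept only if at least `min_fragment` bp. Coordinates are
#' 0-based half-open.
#'
#' @param genomes A contig table restricted to one genome (or more; fragments
#'   keep their `genome_id`).
#' @param config An [ani_config()].
#' @return A tibble with columns `genome_id`, `contig_id`, `start`, `end`,
#'   `sequence`.
#' @export
fragment_genome <- function(genomes, config = ani_config()) {
  check_genomes(genomes)
  L <- config$fragment_length
  purrr::pmap(genomes, function(genome_id, contig_id, sequence, ...) {
    len <- nchar(sequence)
    starts <- seq(0L, max(len - 1L, 0L), by = L)
    ends <- pmin(starts + L, len)
    keep <- (ends - starts) >= config$min_fragment
    if (!any(keep)) return(NULL)
    tibble::tibble(genome_id = genome_id, contig_id = contig_id,
                   start = starts[keep], end = ends[keep],
                   sequence = substring(sequence, starts[keep] + 1L, ends[keep]))
  }) |> dplyr::bind_rows()
}

#' Align one fragment against a subject genome
#'
#' Candidate loci are located through shared `seed_k`-mers on both strands;
#' each candidate is scored by a banded alignment (band width
#' `band_fraction * fragment_length`) and the best hit by identity is
#' reported if it reaches `min_hit_identity` over at least
#' `min_hit_fraction` of the fragment. Identity counts indel columns as
#' mismatches. The absence of a hit is a value, not an error.
#'
#' @param fragment A DNA string (length at least `min_fragment`).
#' @param subject A contig table restricted to the subject genome.
#' @param config An [ani_config()].
#' @return A one-row tibble with `identity`, `frac_aligned`, `hit`;
#'   `identity` is `NA` when no candidate locus exists.
#' @export
align_fragment <- function(fragment, subject, config = ani_config()) {
  check_genomes(subject)
  stopifnot(nchar(fragment) >= config$min_fragment)
  res <- one_way_ani_cpp(fragment, subject$sequence, config$seed_k,
                         as.integer(config$band_fraction * config$fragment_length),
                         config$min_hit_identity, config$min_hit_fraction)
  tibble::tibble(identity = res$identity, frac_aligned = res$frac_aligned,
                 hit = res$hit)
}

#' One-way fragment ANI and alignment coverage
#'
#' ANI is the unweighted mean identity (in percent) over accepted query
#' fragments; coverage is the summed aligned query-fragment length divided
#' by the query's total length, in percent.
#'
#' @param query,subject Contig tables restricted to one genome each.
#' @param config An [ani_config()].
#' @return A one-row tibble with `ani`, `coverage`, `n_fragments`,
#'   `accepted`; `ani` is `NA` when no fragment is accepted.
#' @export
one_way_ani <- function(query, subject, config = ani_config()) {
  frags <- fragment_genome(query, config)
  if (nrow(frags) == 0) stop("query genome yields zero fragments")
  total_len <- sum(nchar(query$sequence))
  res <- one_way_ani_cpp(frags$sequence, subject$sequence, config$seed_k,
                         as.integer(config$band_fraction * config$fragment_length),
                         config$min_hit_identity, config$min_hit_fraction)
  acc <- res$hit
  frag_len <- frags$end - frags$start
  tibble::tibble(
    ani = if (any(acc)) 100 * mean(res$identity[acc]) else NA_real_,
    coverage = 100 * sum(res$frac_aligned[acc] * frag_len[acc]) / total_len,
    n_fragments = nrow(frags),
    accepted = sum(acc))
}

#' Bidirectional fragment ANI for every pair in a genome set
#'
#' One result row per unordered pair (lexicographic order within and across
#' pairs), with both directions computed: `ani_qs`/`cov_q` for query
#' fragments against the subject and `ani_sq`/`cov_s` for the reverse.
#'
#' @param genomes A contig table with at least two genomes.
#' @param config An [ani_config()].
#' @param ids Optional subset of genome ids to compare (defaults to all).
#' @return A tibble with columns `query`, `subject`, `ani_qs`, `cov_q`,
#'   `ani_sq`, `cov_s`, `n_fragments_q`, `n_fragments_s`, `accepted_q`,
#'   `accepted_s`.
#' @export
pairwise_ani <- function(genomes, config = ani_config(),
                         ids = unique(genomes$genome_id)) {
  check_genomes(genomes)
  ids <- sort(ids)
  if (length(ids) < 2) stop("need at least 2 genomes for pairwise ANI")
  split_g <- lapply(ids, function(i) genomes[genomes$genome_id == i, ])
  names(split_g) <- ids
  frags <- lapply(split_g, fragment_genome, config = config)
  empty <- names(frags)[vapply(frags, nrow, integer(1)) == 0]
  if (length(empty) > 0) {
    stop("genome yields zero fragments: ", paste(empty, collapse = ", "))
  }
  total_len <- vapply(split_g, function(g) sum(nchar(g$sequence)), numeric(1))
  band <- as.integer(config$band_fraction * config$fragment_length)

  # all queries against each subject in one pass, so the subject seed index
  # is built once per genome rather than once per pair
  dir_res <- list()
  for (s in ids) {
    queries <- setdiff(ids, s)
    qframes <- frags[queries]
    nfr <- vapply(qframes, nrow, integer(1))
    res <- one_way_ani_cpp(unlist(lapply(qframes, `[[`, "sequence")),
                           split_g[[s]]$sequence, config$seed_k, band,
                           config$min_hit_identity, config$min_hit_fraction)
    grp <- rep(queries, nfr)
    for (q in queries) {
      sel <- grp == q
      acc <- res$hit[sel]
      flen <- (qframes[[q]]$end - qframes[[q]]$start)
      dir_res[[paste(q, s)]] <- tibble::tibble(
        query = q, subject = s,
        ani = if (any(acc)) 100 * mean(res$identity[sel][acc]) else NA_real_,
        coverage = 100 * sum(res$frac_aligned[sel][acc] * flen[acc]) /
          total_len[[q]],
        n_fragments = nfr[[q]], accepted = sum(acc))
    }
  }
  dirs <- dplyr::bind_rows(dir_res)

  pairs <- utils::combn(ids, 2)
  purrr::map(seq_len(ncol(pairs)), function(p) {
    q <- pairs[1, p]; s <- pairs[2, p]
    fwd <- dirs[dirs$query == q & dirs$subject == s, ]
    rev <- dirs[dirs$query == s & dirs$subject == q, ]
    tibble::tibble(query = q, subject = s,
                   ani_qs = fwd$ani, cov_q = fwd$coverage,
                   ani_sq = rev$ani, cov_s = rev$coverage,
                   n_fragments_q = fwd$n_fragments,
                   n_fragments_s = rev$n_fragments,
                   accepted_q = fwd$accepted, accepted_s = rev$accepted)
  }) |> dplyr::bind_rows()
}
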