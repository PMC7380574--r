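#' Configuration of the synthetic conspecific-MAG generator
#'
#' The generator plants species structure with controlled divergence: one
#' ancestor per species, each MAG evolved from its species ancestor so that
#' conspecific pairs sit at `within_ani` percent identity and
#' between-species pairs at `between_ani` (pairwise targets; each branch
#' carries half the divergence). MAGs receive genome-specific auxiliary
#' segments (planted pangenome gene clusters), are fragmented into contigs,
#' and may be subsampled to a drawn completeness.
#'
#' @param n_species Number of planted species.
#' @param mags_per_species Conspecific MAGs per species.
#' @param genome_length Ancestor length in bp (default 200000).
#' @param within_ani Target pairwise ANI between conspecific MAGs, percent
#'   (default 99.5).
#' @param between_ani Target pairwise ANI between species, percent
#'   (default 80). At 90 or above, species ancestors are siblings diverged
#'   from a common root so intermediate, species-boundary ANI regimes are
#'   constructible; below 90 they are independent random sequences.
#' @param indel_rate Per-base indel probability (default 5e-4).
#' @param mean_indel_len Mean indel length in bp (geometric; default 3).
#' @param n_contigs Contigs per MAG (default 20).
#' @param aux_blocks_per_genome Auxiliary gene clusters planted per species,
#'   each carried by a random non-empty subset of its MAGs (default 5).
#' @param aux_block_len Length of each auxiliary segment in bp
#'   (default 2000).
#' @param completeness_range Range the true completeness fraction of each
#'   MAG is drawn from (default `c(1, 1)`: complete genomes).
#' @param seed Integer seed; the whole genome set is reproducible from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_species = 3, mags_per_species = 4,
                         genome_length = 200000, within_ani = 99.5,
                         between_ani = 80, indel_rate = 5e-4,
                         mean_indel_len = 3, n_contigs = 20,
                         aux_blocks_per_genome = 5, aux_block_len = 2000,
                         completeness_range = c(1, 1), seed = 1) {
  stopifnot(within_ani > 0, within_ani <= 100, between_ani < within_ani,
            genome_length >= n_contigs * 1000,
            length(completeness_range) == 2,
            all(completeness_range > 0 & completeness_range <= 1))
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a random ancestral sequence
#'
#' @param length Sequence length in bp (at least 1000).
#' @param seed Integer seed.
#' @return A DNA string of i.i.d. uniform A/C/G/T.
#' @export
generate_ancestor <- function(length, seed = 1) {
  stopifnot(length >= 1000)
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  })
}

#' Evolve a sequence to a target ANI with substitutions and indels
#'
#' Substitutions are placed i.i.d. at rate `1 - target_ani/100` (the new
#' base always differs from the old); indels are placed at `indel_rate`
#' with geometric lengths of the given mean, half insertions and half
#' deletions. The returned mutation mask records every edit in ancestor
#' coordinates and replays exactly through [apply_mutation_mask()].
#'
#' @param ancestor DNA string.
#' @param target_ani Target identity in percent (0, 100\].
#' @param indel_rate Per-base indel probability.
#' @param mean_indel_len Mean indel length (bp).
#' @param seed Integer seed.
#' @return A list with `sequence` (the evolved string) and `mask` (a tibble
#'   with `pos`, `type` in sub/ins/del, `ref`, `alt`).
#' @export
evolve_sequence <- function(ancestor, target_ani, indel_rate = 0,
                            mean_indel_len = 3, seed = 1) {
  stopifnot(target_ani > 0, target_ani <= 100)
  p <- 1 - target_ani / 100
  L <- nchar(ancestor)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
    sub_pos <- which(runif(L) < p)
    alt <- character(length(sub_pos))
    for (i in seq_along(sub_pos)) {
      alt[i] <- sample(setdiff(bases, chars[sub_pos[i]]), 1)
    }
    mask <- tibble::tibble(pos = sub_pos, type = rep("sub", length(sub_pos)),
                           ref = chars[sub_pos], alt = alt)
    if (indel_rate > 0) {
      ind_pos <- which(runif(L) < indel_rate)
      if (length(ind_pos) > 0) {
        ins <- runif(length(ind_pos)) < 0.5
        lens <- rgeom(length(ind_pos), prob = 1 / mean_indel_len) + 1L
        imask <- tibble::tibble(
          pos = ind_pos,
          type = ifelse(ins, "ins", "del"),
          ref = ifelse(ins, "",
                       substring(ancestor, ind_pos,
                                 pmin(ind_pos + lens - 1L, L))),
          alt = ifelse(ins,
                       vapply(lens, function(n)
                         paste(sample(bases, n, replace = TRUE),
                               collapse = ""), character(1)),
                       ""))
        # deletions spanning another edit position replay ambiguously; drop
        if (any(!ins)) {
          del_rows <- which(imask$type == "del")
          all_pos <- c(mask$pos, imask$pos)
          drop <- vapply(del_rows, function(ri) {
            n <- nchar(imask$ref[ri])
            if (n < 2) return(FALSE)
            any(seq(imask$pos[ri] + 1L, imask$pos[ri] + n - 1L) %in% all_pos)
          }, logical(1))
          if (any(drop)) imask <- imask[-del_rows[drop], , drop = FALSE]
        }
        mask <- dplyr::bind_rows(mask, imask)
      }
    }
    mask <- mask[order(mask$pos), , drop = FALSE]
    list(sequence = apply_mutation_mask(ancestor, mask), mask = mask)
  })
}

#' Replay a mutation mask on the ancestor sequence
#'
#' @param ancestor DNA string the mask was generated against.
#' @param mask A mask tibble from [evolve_sequence()].
#' @return The mutated sequence.
#' @export
apply_mutation_mask <- function(ancestor, mask) {
  chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
  out <- as.list(chars)
  for (i in seq_len(nrow(mask))) {
    pos <- mask$pos[i]
    switch(mask$type[i],
           sub = { out[[pos]] <- mask$alt[i] },
           ins = { out[[pos]] <- paste0(chars[pos], mask$alt[i]) },
           del = {
             n <- nchar(mask$ref[i])
             for (jj in seq(pos, pos + n - 1L)) out[[jj]] <- ""
           })
  }
  paste(unlist(out), collapse = "")
}

# split a sequence into n contigs at random breakpoints (min 500 bp apart)
fragment_into_contigs <- function(sequence, n_contigs, genome_id) {
  L <- nchar(sequence)
  if (n_contigs <= 1) {
    return(tibble::tibble(genome_id = genome_id,
                          contig_id = paste0(genome_id, "_c001"),
                          sequence = sequence))
  }
  cuts <- sort(sample(seq(500L, L - 500L), n_contigs - 1))
  while (any(diff(c(0L, cuts, L)) < 200L)) {
    cuts <- sort(sample(seq(500L, L - 500L), n_contigs - 1))
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, L)
  tibble::tibble(genome_id = genome_id,
                 contig_id = sprintf("%s_c%03d", genome_id, seq_along(starts)),
                 sequence = substring(sequence, starts, ends))
}

#' Generate a synthetic MAG set with known ground truth
#'
#' @param config A [synth_config()].
#' @return A list of class `mag_set` with `genomes` (contig table),
#'   `quality` (true completeness with small estimation noise,
#'   contamination 0), `gene_clusters` (one core cluster per species plus
#'   the planted auxiliary clusters), and `truth` (per-genome species
#'   label and true completeness fraction).
#' @export
generate_mag_set <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, 6)
    bases <- c("A", "C", "G", "T")

    root <- generate_ancestor(cfg$genome_length, seed = seeds[1])
    branch_between <- 100 - (100 - cfg$between_ani) / 2
    ancestors <- lapply(seq_len(cfg$n_species), function(sp) {
      if (cfg$between_ani >= 90) {
        evolve_sequence(root, branch_between, indel_rate = 0,
                        seed = seeds[2] + sp)$sequence
      } else {
        generate_ancestor(cfg$genome_length, seed = seeds[2] + sp)
      }
    })

    branch_within <- 100 - (100 - cfg$within_ani) / 2
    genomes <- list(); truth <- list(); gc_rows <- list(); quality <- list()
    for (sp in seq_len(cfg$n_species)) {
      sp_id <- sprintf("sp%02d", sp)
      aux_pool <- lapply(seq_len(cfg$aux_blocks_per_genome), function(b) {
        paste(sample(bases, cfg$aux_block_len, replace = TRUE), collapse = "")
      })
      carriers <- matrix(runif(cfg$mags_per_species *
                                 cfg$aux_blocks_per_genome) < 0.5,
                         nrow = cfg$mags_per_species)
      for (b in seq_len(ncol(carriers))) {
        if (!any(carriers[, b])) {
          carriers[sample.int(cfg$mags_per_species, 1), b] <- TRUE
        }
      }
      for (mg in seq_len(cfg$mags_per_species)) {
        gid <- sprintf("%s_mag%02d", sp_id, mg)
        ev <- evolve_sequence(ancestors[[sp]], branch_within,
                              indel_rate = cfg$indel_rate,
                              mean_indel_len = cfg$mean_indel_len,
                              seed = seeds[3] + 1000L * sp + mg)
        seqn <- ev$sequence
        for (b in which(carriers[mg, ])) {
          at <- sample.int(nchar(seqn) - 1L, 1)
          seqn <- paste0(substring(seqn, 1, at), aux_pool[[b]],
                         substring(seqn, at + 1L))
        }
        contigs <- fragment_into_contigs(seqn, cfg$n_contigs, gid)
        full_len <- sum(nchar(contigs$sequence))
        frac <- runif(1, cfg$completeness_range[1], cfg$completeness_range[2])
        if (frac < 1) {
          contigs <- subsample_to_completeness(
            contigs, frac, seed = seeds[4] + 1000L * sp + mg)
        }
        true_completeness <- sum(nchar(contigs$sequence)) / full_len
        genomes[[gid]] <- contigs
        truth[[gid]] <- tibble::tibble(genome_id = gid, species = sp_id,
                                       true_completeness = true_completeness)
        quality[[gid]] <- tibble::tibble(
          genome_id = gid,
          completeness = pmin(100, pmax(0, 100 * true_completeness +
                                          rnorm(1, 0, 0.5))),
          contamination = 0)
        gc_rows[[gid]] <- tibble::tibble(
          genome_id = gid,
          cluster_id = c(paste0(sp_id, "_core"),
                         sprintf("%s_aux%02d", sp_id, which(carriers[mg, ]))))
      }
    }
    structure(list(genomes = dplyr::bind_rows(genomes),
                   quality = dplyr::bind_rows(quality),
                   gene_clusters = dplyr::bind_rows(gc_rows),
                   truth = dplyr::bind_rows(truth),
                   config = cfg),
              class = "mag_set")
  })
}

#' @export
print.mag_set <- function(x, ...) {
  cat("Synthetic MAG set: ", nrow(x$truth), " genomes, ",
      length(unique(x$truth$species)), " species, ",
      nrow(x$gene_clusters), " gene-cluster memberships\n", sep = "")
  invisible(x)
}

#' Write a synthetic MAG set to disk
#'
#' Writes one FASTA per genome plus `quality.tsv`, `gene_clusters.tsv` and
#' `truth.json` into `outdir`.
#'
#' @param mag_set A `mag_set` from [generate_mag_set()].
#' @param outdir Output directory.
#' @return Invisibly, `outdir`.
#' @export
write_mag_set <- function(mag_set, outdir) {
  stopifnot(inherits(mag_set, "mag_set"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fastas(mag_set$genomes, outdir)
  readr::write_tsv(mag_set$quality, file.path(outdir, "quality.tsv"))
  readr::write_tsv(mag_set$gene_clusters, file.path(outdir, "gene_clusters.tsv"))
  jsonlite::write_json(mag_set$truth, file.path(outdir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(outdir)
}
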