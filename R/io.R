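#' Read a directory of genome FASTA files into a tidy contig table
#'
#' Each file becomes one genome (a MAG); the genome id is the file name
#' without its extension. Sequences are upper-cased and `U` is normalised to
#' `T` on ingest; characters outside `A`, `C`, `G`, `T`, `N` are rejected.
#'
#' @param path Directory containing one multi-FASTA file per genome.
#' @param pattern Glob-style file pattern (default `"*.fasta"`; `.fa` and
#'   `.fna` files are also picked up by the default).
#' @return A tibble with columns `genome_id`, `contig_id`, `sequence`,
#'   ordered lexicographically by genome id. This contig table is the genome
#'   container used throughout the package.
#' @export
read_genome_dir <- function(path, pattern = c("*.fasta", "*.fa", "*.fna")) {
  if (!dir.exists(path)) stop("genome directory does not exist: ", path)
  files <- sort(unique(unlist(lapply(pattern, function(p) {
    Sys.glob(file.path(path, p))
  }))))
  if (length(files) == 0) stop("no FASTA files matching pattern in ", path)
  ids <- sub("\\.[^.]*$", "", basename(files))
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids after stripping extensions: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tabs <- purrr::map2(files, ids, read_genome_fasta)
  out <- dplyr::bind_rows(tabs)
  out[order(out$genome_id), , drop = FALSE]
}

#' Read one multi-FASTA file as a single genome
#'
#' @param file Path to a FASTA file.
#' @param genome_id Genome id; defaults to the file stem.
#' @return A tibble with columns `genome_id`, `contig_id`, `sequence`.
#' @export
read_genome_fasta <- function(file, genome_id = sub("\\.[^.]*$", "", basename(file))) {
  seqs <- tryCatch(Biostrings::readBStringSet(file),
                   error = function(e) stop("cannot parse FASTA file ", file,
                                            ": ", conditionMessage(e)))
  if (length(seqs) == 0) stop("empty FASTA file: ", file)
  contig_ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(contig_ids)) {
    stop("duplicate contig ids in ", file, ": ",
         paste(unique(contig_ids[duplicated(contig_ids)]), collapse = ", "))
  }
  sequence <- chartr("U", "T", toupper(as.character(seqs)))
  bad <- stringr::str_detect(sequence, "[^ACGTN]")
  if (any(bad)) {
    ch <- stringr::str_extract(sequence[bad][1], "[^ACGTN]")
    stop("invalid sequence character '", ch, "' in file ", file,
         ", contig ", contig_ids[bad][1])
  }
  tibble::tibble(genome_id = genome_id, contig_id = contig_ids,
                 sequence = unname(sequence))
}

#' Per-genome summary of a contig table
#'
#' @param genomes A contig table from [read_genome_dir()].
#' @return A tibble with `genome_id`, `n_contigs`, `total_length`.
#' @export
genome_stats <- function(genomes) {
  check_genomes(genomes)
  genomes |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(n_contigs = dplyr::n(),
                     total_length = sum(nchar(.data$sequence)),
                     .groups = "drop")
}

check_genomes <- function(genomes) {
  stopifnot(is.data.frame(genomes),
            all(c("genome_id", "contig_id", "sequence") %in% names(genomes)))
  dup <- duplicated(genomes[c("genome_id", "contig_id")])
  if (any(dup)) stop("duplicate contig ids within a genome")
  invisible(genomes)
}

#' Read a genome quality table
#'
#' A tab-separated table with header columns `genome_id`, `completeness`
#' (percent in \[0, 100\]) and `contamination` (percent, non-negative), as
#' estimated by an external quality tool. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the three columns, one row per genome.
#' @export
read_quality_table <- function(path) {
  tab <- suppressWarnings(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(
                      genome_id = readr::col_character(),
                      completeness = readr::col_double(),
                      contamination = readr::col_double())))
  missing <- setdiff(c("genome_id", "completeness", "contamination"), names(tab))
  if (length(missing) > 0) {
    stop("quality table is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad_c <- which(is.na(tab$completeness) | tab$completeness < 0 | tab$completeness > 100)
  if (length(bad_c) > 0) {
    stop("completeness outside [0, 100] at row ", bad_c[1])
  }
  bad_x <- which(is.na(tab$contamination) | tab$contamination < 0)
  if (length(bad_x) > 0) {
    stop("negative or missing contamination at row ", bad_x[1])
  }
  tibble::as_tibble(tab[c("genome_id", "completeness", "contamination")])
}

#' Read a gene-cluster membership table
#'
#' A tab-separated table with header columns `genome_id` and `cluster_id`;
#' one row per (genome, gene cluster) membership. Duplicate rows collapse to
#' a single membership. A gene cluster is a pangenome unit: a set of
#' homologous genes across genomes.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `genome_id`, `cluster_id` (distinct rows).
#' @export
read_gene_cluster_table <- function(path) {
  tab <- suppressWarnings(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(
                      genome_id = readr::col_character(),
                      cluster_id = readr::col_character())))
  missing <- setdiff(c("genome_id", "cluster_id"), names(tab))
  if (length(missing) > 0) {
    stop("gene-cluster table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  dplyr::distinct(tibble::as_tibble(tab[c("genome_id", "cluster_id")]))
}

write_tsv_commented <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Write dereplication report tables
#'
#' Writes `clusters.tsv` (per-genome assignment: pre-cluster, secondary
#' cluster, kept flag, representative, quality score), `ani_pairs.tsv`
#' (per-pair bidirectional ANI/coverage and the pass decision) and
#' `representatives.tsv` (one retained genome id per line) into `outdir`.
#' The tables round-trip losslessly through [read_report_tables()].
#'
#' @param report A `derep_report` from [run_pipeline()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report_tables <- function(report, outdir) {
  stopifnot(inherits(report, "derep_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- c(clusters = file.path(outdir, "clusters.tsv"),
             pairs = file.path(outdir, "ani_pairs.tsv"),
             representatives = file.path(outdir, "representatives.tsv"))
  readr::write_tsv(report$clusters, paths[["clusters"]])
  readr::write_tsv(report$pairs, paths[["pairs"]])
  readr::write_tsv(report$clusters[report$clusters$kept, "genome_id"],
                   paths[["representatives"]])
  invisible(paths)
}

#' Read dereplication report tables back into a report object
#'
#' @param outdir Directory written by [write_report_tables()].
#' @return A `derep_report` with the `clusters` and `pairs` tables.
#' @export
read_report_tables <- function(outdir) {
  clusters <- readr::read_tsv(file.path(outdir, "clusters.tsv"),
                              show_col_types = FALSE,
                              col_types = readr::cols(
                                genome_id = readr::col_character(),
                                precluster = readr::col_integer(),
                                secondary_cluster = readr::col_integer(),
                                kept = readr::col_logical(),
                                representative = readr::col_character(),
                                score = readr::col_double()))
  pairs <- readr::read_tsv(file.path(outdir, "ani_pairs.tsv"),
                           show_col_types = FALSE,
                           col_types = readr::cols(
                             query = readr::col_character(),
                             subject = readr::col_character(),
                             n_fragments_q = readr::col_integer(),
                             n_fragments_s = readr::col_integer(),
                             accepted_q = readr::col_integer(),
                             accepted_s = readr::col_integer(),
                             pass = readr::col_logical(),
                             .default = readr::col_double()))
  new_derep_report(clusters = tibble::as_tibble(clusters),
                   pairs = tibble::as_tibble(pairs))
}

#' Write a genome contig table to FASTA files (one per genome)
#'
#' @param genomes A contig table.
#' @param outdir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_genome_fastas <- function(genomes, outdir) {
  check_genomes(genomes)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(genomes$genome_id)
  paths <- character(length(ids))
  for (i in seq_along(ids)) {
    g <- genomes[genomes$genome_id == ids[i], ]
    set <- Biostrings::DNAStringSet(setNames(g$sequence, g$contig_id))
    paths[i] <- file.path(outdir, paste0(ids[i], ".fasta"))
    Biostrings::writeXStringSet(set, paths[i])
  }
  invisible(paths)
}
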