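# Shared fixtures: everything is generated in code at test time.

rand_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

make_genome <- function(id, seqs) {
  tibble::tibble(genome_id = id,
                 contig_id = sprintf("%s_c%02d", id, seq_along(seqs)),
                 sequence = seqs)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Independent brute-force oracle for the canonical k-mer Jaccard: for odd k
# no k-mer is its own reverse complement, so the Jaccard of the
# both-strand k-mer sets equals the Jaccard of the canonical sets.
kmer_set_both_strands <- function(seqs, k) {
  out <- character(0)
  for (s in c(seqs, revcomp_chr(seqs))) {
    n <- nchar(s)
    if (n < k) next
    out <- c(out, substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1))
  }
  unique(out[!grepl("N", out, fixed = TRUE)])
}

oracle_jaccard <- function(seqs_a, seqs_b, k) {
  a <- kmer_set_both_strands(seqs_a, k)
  b <- kmer_set_both_strands(seqs_b, k)
  length(intersect(a, b)) / length(union(a, b))
}

write_fasta_dir <- function(genomes, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_genome_fastas(genomes, dir)
  dir
}

# small conspecific set shared by several tests (built once per run)
local_small_mag_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_mag_set(synth_config(
        n_species = 2, mags_per_species = 3, genome_length = 60000,
        n_contigs = 10, aux_blocks_per_genome = 3, seed = 404))
    }
    cache
  }
})
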