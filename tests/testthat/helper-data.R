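# Shared fixtures, generated in code.

# A small labeled transcript table with known composition.
toy_transcripts <- function(n_per_class = 10L, seed = 42L) {
  cfg <- synth_config(n_pos = n_per_class, n_neg = n_per_class,
                      len_range = c(210L, 260L), effect = "strong",
                      seed = seed)
  gen_dataset(cfg)
}

# Random A/C/G/T sequence, independent of the package generator.
random_seq <- function(len) {
  paste(sample(c("A", "T", "C", "G"), len, replace = TRUE), collapse = "")
}

# Write a transcript table to a temporary FASTA file.
tmp_fasta <- function(tr) {
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", tr$id, "\n", tr$seq), path)
  path
}
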