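# Fixture builders (everything is generated in code; no binary data).

write_fasta_text <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

fixture_trinuc_path <- function() {
  system.file("extdata", "trinuc_weights_synthetic_example.tsv",
              package = "cisrobust", mustWork = TRUE)
}

# Promoter alignment whose conservation is confined to the proximal
# `conserved_bp` (the ~250 bp core): the two rows agree over the 3'
# portion bar sparse mismatches and are independently random over the
# distal portion. Returns the alignment file path and the reference length.
fixture_boundary_alignment <- function(total_bp = 1200, conserved_bp = 250,
                                       mismatch_every = 40, seed = 42) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), total_bp, replace = TRUE)
  other <- sample(c("A", "C", "G", "T"), total_bp, replace = TRUE)
  core <- (total_bp - conserved_bp + 1):total_bp  # 3' end abuts the ATG
  other[core] <- ref[core]
  mm <- core[seq(mismatch_every %/% 2, conserved_bp, by = mismatch_every)]
  for (i in mm) {
    alt <- setdiff(c("A", "C", "G", "T"), ref[i])
    other[i] <- alt[1]
  }
  path <- write_fasta_text(list(cel = paste(ref, collapse = ""),
                                cbr = paste(other, collapse = "")),
                           tempfile(fileext = ".afa"))
  list(path = path, ref_length = total_bp)
}

# random gapped pairwise/multiple alignment for oracle tests
random_alignment <- function(ncol = 60, nrow_aln = 2, p_gap = 0.08,
                             p_match = 0.7) {
  ref <- sample(c("A", "C", "G", "T"), ncol, replace = TRUE)
  rows <- list(ref)
  for (r in seq_len(nrow_aln - 1)) {
    row <- ifelse(runif(ncol) < p_match, ref,
                  sample(c("A", "C", "G", "T", "N", "-"), ncol,
                         replace = TRUE))
    rows <- c(rows, list(row))
  }
  # gap the reference sparsely, keeping enough ungapped positions
  gap_ref <- runif(ncol) < p_gap
  ref[gap_ref] <- "-"
  rows[[1]] <- ref
  vapply(rows, paste, character(1), collapse = "")
}

make_ds <- function(d_count, strain = "FL", temperature = 20,
                    dvb = TRUE, int_d = 1000, int_dvb = 1000) {
  n <- length(d_count)
  data.frame(strain = strain, temperature_c = temperature,
             d_count = as.integer(d_count),
             dvb_expressed = rep_len(dvb, n),
             intensity_d = rep_len(int_d, n),
             intensity_dvb = rep_len(int_dvb, n))
}

expr_fixture_tsv <- function(ds, path = tempfile(fileext = ".tsv")) {
  write_expression_table(ds, path)
  path
}
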