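# shared fixtures: small random two-group samples and brute-force oracles

random_sample <- function(n_max = 30, meanlog = 3, sdlog = 1) {
  n_a <- sample(2:n_max, 1)
  n_b <- sample(2:n_max, 1)
  list(a = rlnorm(n_a, meanlog, sdlog), b = rlnorm(n_b, meanlog, sdlog))
}

# independent oracle: enumerate all ordered cross pairs explicitly
brute_pairs_lr <- function(a, b, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  vals <- as.vector(outer(log2(b), log2(a), "-"))
  if (agg == "mean") mean(vals) else median(vals)
}

# hand-written 3-variable fixture matrix + labels written to temp files
write_tiny_matrix <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mat_path <- file.path(dir, "tiny_matrix.tsv")
  lab_path <- file.path(dir, "tiny_labels.tsv")
  writeLines(c(
    "id\ts1\ts2\ts3\ts4",
    "g1\t1\t2\t4\t8",
    "g2\t10\t10\t30\t30",
    "g3\t5\t6\t5\t7"), mat_path)
  writeLines(c(
    "sample_id\tgroup",
    "s1\treference", "s2\treference",
    "s3\ttreatment", "s4\ttreatment"), lab_path)
  list(matrix = mat_path, labels = lab_path, dir = dir)
}
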