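# Small programmatic fixtures shared across test files.

# a tiny complete dosage matrix with ids
toy_dosage <- function(n = 12, m = 30, seed = 101, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.2, 0.8)
  X <- sapply(p, function(pp) rbinom(n, 2, pp))
  dimnames(X) <- list(sprintf("T%02d", seq_len(n)),
                      sprintf("M%02d", seq_len(m)))
  X
}

# genotype CSV text on disk; returns the path
write_toy_genotype_csv <- function(dir = tempdir()) {
  path <- file.path(dir, "toy_geno.csv")
  writeLines(c("id,family,M1,M2,M3",
               "G01,F1,0,1,2",
               "G02,F1,NA,2,0",
               "G03,F2,1,,1",
               "G04,F2,2,0,-9"), path)
  path
}

# minimal plain-text VCF with one multiallelic record
write_toy_vcf <- function(dir = tempdir()) {
  path <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1\t0/0",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1\t1/1",
    "1\t300\trs3\tG\tA,T\t.\tPASS\t.\tGT\t0/1\t0/2\t1/1",
    "1\t400\trs4\tT\tC\t.\tPASS\t.\tGT\t1/1\t0/0\t0|1"), path)
  path
}

# a small simulated dataset shared by slower tests (computed once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_progenies = 6, fam_size = 10, n_markers = 120,
                        n_qtl = 40, h2 = 0.4, seed = 77)
      cache <<- c(simulate_dataset(cfg), list(cfg = cfg))
    }
    cache
  }
})
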