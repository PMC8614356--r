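# shared in-code fixtures

# random acyclic pedigree: animals added sequentially, parents (possibly
# unknown) drawn from earlier animals; shallow enough for the path oracle
random_pedigree <- function(n, p_parent = 0.7) {
  animal <- sprintf("A%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) < p_parent) {
      pick <- sample(i - 1L, 2L)
      sire[i] <- animal[pick[1]]
      dam[i] <- animal[pick[2]]
    }
  }
  ped_table(animal, sire, dam)
}

# genotype vector + positions for ROH tests
random_roh_instance <- function(max_snps = 200, spacing_bp = 60000,
                                p = c(hom_ref = 0.55, het = 0.12,
                                      hom_alt = 0.25, miss = 0.08)) {
  n <- sample(20:max_snps, 1)
  calls <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE, prob = p)
  pos <- sort(sample.int(n * spacing_bp, n))
  list(calls = calls, pos = pos)
}

# small genotype fixture: 3 animals x 5 SNPs over 2 chromosomes
tiny_genotypes <- function() {
  map <- snp_map(paste0("s", 1:5), c(1, 1, 1, 2, 2),
                 c(1e6, 2e6, 3e6, 1e6, 2e6))
  calls <- rbind(c(0L, 1L, 2L, 0L, NA),
                 c(0L, 0L, 0L, 1L, 2L),
                 c(2L, 1L, 0L, 0L, 0L))
  list(genotypes = genotype_matrix(calls, c("a1", "a2", "a3"), map),
       map = map)
}

expect_same_segments <- function(a, b) {
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}
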