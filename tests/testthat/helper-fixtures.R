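# Shared fixtures, built in code.

# the ten-marker worked example
tbl1 <- table1_example()
tbl1_part <- partition_effects(tbl1$effects, "higher")

# a small genome for simulator tests: 2 chromosomes x 50 markers, 100 cM
small_genome <- function() sim_genome(n_chrom = 2, n_markers = 100, total_cM = 200)

# random origin-coded genotype matrix of inbred-ish lines
rand_geno <- function(n, m, het = 0) {
  vals <- if (het > 0) c(-1, 0, 1) else c(-1, 1)
  prob <- if (het > 0) c((1 - het) / 2, het, (1 - het) / 2) else c(0.5, 0.5)
  W <- matrix(sample(vals, n * m, TRUE, prob), n, m)
  dimnames(W) <- list(paste0("L", seq_len(n)), paste0("M", seq_len(m)))
  W
}

# brute-force two-sample KS statistic by evaluating both ECDFs at every
# observed point
ks_D_bruteforce <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}
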