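# Simulated bi-parental populations.
#
# Each individual is a pair of gametic haplotypes stored as integer vectors
# over all markers: 0 = allele from the primary parent, 1 = allele from the
# secondary parent. The origin-coded genotype is h1 + h2 - 1. Meiosis uses
# a Poisson crossover count per chromosome (mean = length in Morgan),
# uniform crossover positions and no interference, i.e. Haldane-consistent
# recombination fractions.

new_sim_pop <- function(h1, h2, genome, generation, lines = NULL) {
  lines <- lines %||% paste0("L", formatC(seq_len(nrow(h1)), width = 4, flag = "0"))
  rownames(h1) <- rownames(h2) <- lines
  structure(list(h1 = h1, h2 = h2, genome = genome, generation = generation),
            class = "sim_pop")
}

#' @export
print.sim_pop <- function(x, ...) {
  het <- mean(x$h1 != x$h2)
  cat("Simulated population (", x$generation, "): ", nrow(x$h1), " lines x ",
      x$genome$n_markers, " markers, mean heterozygosity ",
      signif(het, 3), "\n", sep = "")
  invisible(x)
}

#' Number of lines in a simulated population
#' @param pop A `sim_pop`.
#' @return Integer count.
#' @export
n_lines <- function(pop) nrow(pop$h1)

#' Origin-coded genotypes of a simulated population
#'
#' @param pop A `sim_pop`.
#' @return Integer matrix (lines x markers) with values -1 (homozygous
#'   primary), 0 (heterozygous), +1 (homozygous secondary).
#' @export
genotypes <- function(pop) {
  G <- pop$h1 + pop$h2 - 1L
  colnames(G) <- pop$genome$markers
  G
}

# One gamete from the individual with haplotypes h1, h2 (vectors over all
# markers). Crossover breakpoints are drawn per chromosome but applied in
# one pass over the global marker coordinates.
r_gamete <- function(h1, h2, geo) {
  n_co <- rpois(geo$n_chrom, geo$chrom_length / 100)
  start1 <- runif(geo$n_chrom) < 0.5
  K <- sum(n_co)
  if (K == 0L) {
    use1 <- rep(start1, each = geo$markers_per_chrom)
  } else {
    bp <- sort.int(rep.int(geo$starts, n_co) + runif(K) * geo$chrom_length)
    seg <- findInterval(geo$gpos, bp)
    before <- cumsum(c(0L, n_co))[seq_len(geo$n_chrom)]
    seg_within <- seg - rep(before, each = geo$markers_per_chrom)
    use1 <- (seg_within %% 2L == 0L) == rep(start1, each = geo$markers_per_chrom)
  }
  out <- h2
  out[use1] <- h1[use1]
  out
}

#' Sample gametes from individuals of a population
#'
#' @param pop A `sim_pop`.
#' @param id Line index or name of the parent.
#' @param n Number of independent gametes.
#' @return Integer matrix (`n` x markers) of gametic haplotypes
#'   (0 = primary allele, 1 = secondary allele).
#' @export
sim_gametes <- function(pop, id = 1, n = 1) {
  if (is.character(id)) id <- match(id, rownames(pop$h1))
  h1 <- pop$h1[id, ]
  h2 <- pop$h2[id, ]
  out <- matrix(0L, n, pop$genome$n_markers)
  for (i in seq_len(n)) out[i, ] <- r_gamete(h1, h2, pop$genome)
  colnames(out) <- pop$genome$markers
  out
}

founder_haplotype <- function(genome, allele) {
  rep(as.integer(allele), genome$n_markers)
}

#' The two inbred founders of the cross
#'
#' A two-line population holding the fully homozygous primary parent
#' (line `P`, genotype -1 everywhere) and secondary parent (line `S`,
#' genotype +1 everywhere).
#'
#' @param genome A [sim_genome()].
#' @return A `sim_pop` with lines `P` and `S`.
#' @export
founders <- function(genome = sim_genome()) {
  h <- rbind(founder_haplotype(genome, 0), founder_haplotype(genome, 1))
  new_sim_pop(h, h, genome, "founders", c("P", "S"))
}

#' Found a bi-parental base population
#'
#' Builds the immediate offspring generation of a cross between the two
#' inbred founders: `F2` individuals are offspring of F1 x F1, `BC1` of
#' F1 x primary parent and `rBC1` of F1 x secondary parent (the secondary
#' line as recurrent parent).
#'
#' @param type `"F2"`, `"BC1"` or `"rBC1"`.
#' @param n Population size.
#' @param genome A [sim_genome()].
#' @return A `sim_pop`.
#' @export
found_population <- function(type = c("F2", "BC1", "rBC1"), n, genome = sim_genome()) {
  type <- match.arg(type)
  if (n < 1) abort("population size must be at least 1")
  f1a <- founder_haplotype(genome, 0)
  f1b <- founder_haplotype(genome, 1)
  h1 <- matrix(0L, n, genome$n_markers)
  h2 <- matrix(0L, n, genome$n_markers)
  for (i in seq_len(n)) {
    h1[i, ] <- r_gamete(f1a, f1b, genome)
    h2[i, ] <- switch(type,
      F2 = r_gamete(f1a, f1b, genome),
      BC1 = f1a,
      rBC1 = f1b
    )
  }
  new_sim_pop(h1, h2, genome, type)
}

#' Advance a population by single-seed descent
#'
#' Each line is replaced by one selfed offspring per generation, keeping
#' the population size constant. Selfing never increases heterozygosity;
#' the expected per-marker heterozygosity halves each generation.
#'
#' @param pop A `sim_pop`.
#' @param g Number of selfing generations (`g = 0` returns the input).
#' @return A `sim_pop` labelled `<generation>S<g>`.
#' @export
self_generations <- function(pop, g) {
  if (g < 0) abort("g must be non-negative")
  if (g == 0) return(pop)
  geo <- pop$genome
  h1 <- pop$h1
  h2 <- pop$h2
  for (gen in seq_len(g)) {
    for (i in seq_len(nrow(h1))) {
      a <- r_gamete(h1[i, ], h2[i, ], geo)
      b <- r_gamete(h1[i, ], h2[i, ], geo)
      h1[i, ] <- a
      h2[i, ] <- b
    }
  }
  new_sim_pop(h1, h2, geo, paste0(pop$generation, "S", g), rownames(pop$h1))
}

#' Double haploids from a cross of two lines
#'
#' Makes the F1 of the two parents (one gamete from each), then derives
#' each double haploid by doubling one recombinant gamete of that F1.
#' Every DH is fully homozygous.
#'
#' @param pop A `sim_pop` holding the parents.
#' @param parent1,parent2 Line names or indices of the two parents.
#' @param n_dh Number of double haploids.
#' @param prefix Line-name prefix for the new DHs.
#' @return A `sim_pop` of `n_dh` fully homozygous lines.
#' @export
make_dh <- function(pop, parent1, parent2, n_dh, prefix = "DH") {
  if (n_dh < 1) abort("n_dh must be at least 1")
  geo <- pop$genome
  f1_h1 <- drop(sim_gametes(pop, parent1, 1))
  f1_h2 <- drop(sim_gametes(pop, parent2, 1))
  h <- matrix(0L, n_dh, geo$n_markers)
  for (i in seq_len(n_dh)) h[i, ] <- r_gamete(f1_h1, f1_h2, geo)
  new_sim_pop(h, h, geo, "DH",
              paste0(prefix, formatC(seq_len(n_dh), width = 3, flag = "0")))
}

# internal: fast numeric true BVs
.true_bv <- function(pop, qtl) {
  G <- pop$h1[, qtl$qtl$index, drop = FALSE] + pop$h2[, qtl$qtl$index, drop = FALSE] - 1L
  unname(drop(G %*% qtl$qtl$effect))
}

#' True breeding values under a QTL model
#'
#' `BV = sum_j g_j u_j` over the QTL markers, with `g` in origin coding.
#'
#' @param pop A `sim_pop`.
#' @param qtl A [sample_qtl_model()] result.
#' @return A tibble with columns `line`, `bv`.
#' @export
true_bv <- function(pop, qtl) {
  tibble::tibble(line = rownames(pop$h1), bv = .true_bv(pop, qtl))
}

#' Simulate phenotypes
#'
#' `y = BV + e` with i.i.d. standard normal residuals, the residual law
#' used throughout the simulation study (unit residual variance, so the
#' realized heritability is `Var(BV) / (Var(BV) + 1)`).
#'
#' @param pop A `sim_pop`.
#' @param qtl A [sample_qtl_model()] result.
#' @return A tibble with columns `line`, `bv`, `y`.
#' @export
sim_phenotype <- function(pop, qtl) {
  bv <- .true_bv(pop, qtl)
  tibble::tibble(line = rownames(pop$h1), bv = bv, y = bv + rnorm(length(bv)))
}

# internal: per-line favorable-allele proportions given index/class sets
.favorable_prop <- function(pop, idx_P, idx_S, denom) {
  GP <- pop$h1[, idx_P, drop = FALSE] + pop$h2[, idx_P, drop = FALSE] - 1L
  GS <- pop$h1[, idx_S, drop = FALSE] + pop$h2[, idx_S, drop = FALSE] - 1L
  list(P = unname(rowSums(1 - GP)) / (2 * denom),
       S = unname(rowSums(1 + GS)) / (2 * denom))
}

#' Per-line proportions of favorable parental alleles
#'
#' For each line, `P` is its average dosage of the favorable allele over
#' QTL (or markers) whose favorable allele comes from the primary parent:
#' `P = (1/p) * sum_{j in P} (1 - g_j)/2`, and `S` the secondary-parent
#' analogue `(1/p) * sum_{j in S} (1 + g_j)/2`. With a [sample_qtl_model()]
#' the sums run over QTL and `p` is the total QTL count (so the primary
#' parent of a 60:40 model scores `P = 0.60, S = 0`); with an
#' [partition_effects()] object they run over the classified markers and
#' `p` is the total marker count.
#'
#' @param pop A `sim_pop`.
#' @param model A `qtl_model` or an `effect_partition`.
#' @return A tibble with columns `line`, `P`, `S`.
#' @export
favorable_proportions <- function(pop, model) {
  if (inherits(model, "qtl_model")) {
    pr <- .favorable_prop(pop, model$qtl$index[model$qtl$class == "P"],
                          model$qtl$index[model$qtl$class == "S"], model$p)
  } else if (inherits(model, "effect_partition")) {
    pr <- .favorable_prop(pop, which(model$class == "P"),
                          which(model$class == "S"), nrow(model))
  } else {
    abort("model must be a qtl_model or an effect_partition")
  }
  tibble::tibble(line = rownames(pop$h1), P = pr$P, S = pr$S)
}

# subset a population by line names or indices
subset_pop <- function(pop, ids) {
  if (is.character(ids)) ids <- match(ids, rownames(pop$h1))
  new_sim_pop(pop$h1[ids, , drop = FALSE], pop$h2[ids, , drop = FALSE],
              pop$genome, pop$generation, rownames(pop$h1)[ids])
}

# bind populations over the same genome
bind_pops <- function(pops, generation) {
  new_sim_pop(do.call(rbind, lapply(pops, `[[`, "h1")),
              do.call(rbind, lapply(pops, `[[`, "h2")),
              pops[[1]]$genome, generation,
              unlist(lapply(pops, function(p) rownames(p$h1))))
}
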