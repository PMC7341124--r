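#' Define a simulated genome
#'
#' Markers are spread evenly over equally sized chromosomes: with spacing
#' `s = total_cM / n_markers`, the markers of each chromosome sit at
#' `s/2, 3s/2, ...`, so adjacent markers are exactly `s` cM apart. The
#' default genome is 10 chromosomes carrying 7,750 markers over 1,550 cM
#' (775 markers per 155 cM chromosome, 0.2 cM spacing).
#'
#' @param n_chrom Number of chromosomes.
#' @param n_markers Total marker count; must be divisible by `n_chrom`.
#' @param total_cM Total genetic length in centimorgan.
#' @return An object of class `sim_genome`.
#' @export
sim_genome <- function(n_chrom = 10, n_markers = 7750, total_cM = 1550) {
  if (n_markers %% n_chrom != 0) {
    abort("n_markers must be divisible by n_chrom for an even layout")
  }
  m_per <- n_markers / n_chrom
  chrom_len <- total_cM / n_chrom
  spacing <- total_cM / n_markers
  pos <- (seq_len(m_per) - 0.5) * spacing
  starts <- (seq_len(n_chrom) - 1) * chrom_len
  markers <- paste0("C", formatC(rep(seq_len(n_chrom), each = m_per), width = 2, flag = "0"),
                    "M", formatC(rep(seq_len(m_per), n_chrom), width = 4, flag = "0"))
  structure(list(
    n_chrom = as.integer(n_chrom), n_markers = as.integer(n_markers),
    total_cM = total_cM, markers_per_chrom = as.integer(m_per),
    chrom_length = chrom_len, spacing = spacing,
    markers = markers,
    chromosome = rep(seq_len(n_chrom), each = m_per),
    pos = rep(pos, n_chrom),
    gpos = rep(starts, each = m_per) + rep(pos, n_chrom),
    starts = starts
  ), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("Simulated genome:", x$n_chrom, "chromosomes,", x$n_markers,
      "markers,", x$total_cM, "cM total\n")
  cat("  ", x$markers_per_chrom, "markers per", x$chrom_length,
      "cM chromosome (", x$spacing, "cM spacing )\n")
  invisible(x)
}

#' Genetic map of a simulated genome
#'
#' @param genome A [sim_genome()].
#' @return A [genetic_map()] tibble with columns `marker`, `chromosome`,
#'   `cM`.
#' @export
genome_map <- function(genome) {
  genetic_map(tibble::tibble(
    marker = genome$markers,
    chromosome = genome$chromosome,
    cM = genome$pos
  ))
}

#' Sample a QTL model on a simulated genome
#'
#' QTL positions are drawn uniformly without replacement from the markers.
#' The number of QTL is `p = round(total_cM / density_cM_per_qtl)`; a
#' fraction `ratio_P` of them (rounded) carry their favorable allele from
#' the primary parent (class `P`, negative effect under origin coding and
#' favorable direction "higher"), the rest from the secondary parent
#' (class `S`, positive effect). Effect magnitudes are half-normal with
#' scale `1/sqrt(p)`, so each QTL has `E[u^2] = 1/p` and the aggregated
#' QTL variance is 1 by construction, identically for the two classes.
#'
#' @param genome A [sim_genome()].
#' @param density_cM_per_qtl Genetic distance per QTL in cM (2 gives a
#'   dense, 20 a sparse architecture on the default genome).
#' @param ratio_P Proportion of QTL whose favorable allele is from the
#'   primary parent, in `[0, 1]`.
#' @return An object of class `qtl_model`: list with `qtl` (tibble of
#'   `marker`, `index`, `class`, `effect`), `p`, `n_P`, `n_S`.
#' @export
sample_qtl_model <- function(genome, density_cM_per_qtl = 2, ratio_P = 0.5) {
  p <- round(genome$total_cM / density_cM_per_qtl)
  if (p < 1 || p > genome$n_markers) {
    abort("QTL density yields a QTL count outside [1, n_markers]")
  }
  if (ratio_P < 0 || ratio_P > 1) abort("ratio_P must be in [0, 1]")
  n_P <- round(ratio_P * p)
  n_S <- p - n_P
  idx <- sort.int(sample.int(genome$n_markers, p))
  cls <- sample(c(rep("P", n_P), rep("S", n_S)))
  mag <- abs(rnorm(p, 0, sqrt(1 / p)))
  structure(list(
    qtl = tibble::tibble(
      marker = genome$markers[idx],
      index = idx,
      class = cls,
      effect = ifelse(cls == "P", -mag, mag)
    ),
    p = p, n_P = n_P, n_S = n_S
  ), class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat("QTL model:", x$p, "QTL (", x$n_P, "favorable-primary,", x$n_S,
      "favorable-secondary ), aggregate E[sum u^2] = 1\n")
  invisible(x)
}

#' Expand a QTL model to a genome-wide effect partition
#'
#' Builds the full-length marker-effect vector implied by a QTL model
#' (zero off the QTL) as an [partition_effects()] object, which makes the
#' simulator's true breeding values reproducible through
#' [predict_breeding_values()].
#'
#' @param qtl A [sample_qtl_model()] result.
#' @param genome The [sim_genome()] the model was drawn on.
#' @return An `effect_partition` tibble over all markers.
#' @export
qtl_partition <- function(qtl, genome) {
  u <- rep(0, genome$n_markers)
  u[qtl$qtl$index] <- qtl$qtl$effect
  partition_effects(setNames(u, genome$markers), "higher")
}
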