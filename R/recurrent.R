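# Recurrent GS/OSGS selection on simulated populations, and the
# fold-change / contrast metrics used to summarise outcomes.

pop_metrics <- function(pop, qtl, partition) {
  pr <- .favorable_prop(pop, qtl$qtl$index[qtl$qtl$class == "P"],
                        qtl$qtl$index[qtl$qtl$class == "S"], qtl$p)
  tibble::tibble(
    mu_BV = mean(.true_bv(pop, qtl)),
    mu_P = mean(pr$P),
    mu_S = mean(pr$S),
    mu_EBV = mean(drop(genotypes(pop) %*% partition$effect))
  )
}

select_and_advance <- function(pop, partition, method, omega, top_k, n_dh, cycle) {
  bv <- predict_breeding_values(genotypes(pop), partition)
  index <- if (method == "GS") gs_index(bv) else osgs_index(bv, omega)
  sel <- select_top(index, top_k)
  crosses <- half_diallel(sel$line)
  dhs <- vector("list", nrow(crosses))
  for (j in seq_len(nrow(crosses))) {
    dhs[[j]] <- make_dh(pop, crosses$parent1[j], crosses$parent2[j], n_dh,
                        prefix = paste0("c", cycle, "x", formatC(j, width = 2, flag = "0"), "d"))
  }
  bind_pops(dhs, paste0("cycle", cycle))
}

#' Run recurrent genomic selection on a simulated breeding program
#'
#' Reproduces the simulated introgression study: a bi-parental base
#' population is founded (`F2`, `BC1` or `rBC1`), advanced by `n_self`
#' generations of single-seed descent, and phenotyped once with unit
#' residual variance. Ridge-BLUP marker effects are estimated once on
#' that cycle-0 data (unless `retrain = TRUE`) and partitioned by origin.
#' Each cycle then predicts breeding values with those effects, selects
#' the `top_k` lines by the configured index (GS on `a_hat`, or the OSGS
#' rank index at weight `omega`), crosses them in a half diallel and
#' builds the next cycle from `n_dh` double haploids per cross. With the
#' defaults (`top_k = 5`, `n_dh = 20`) the population size stays at 200.
#'
#' When several methods are given they share the same QTL model, base
#' population and cycle-0 fit within each replicate, so method contrasts
#' are paired. Replicate seeds are drawn from `seed` by one
#' `sample.int()` call, so runs are fully reproducible.
#'
#' @param pop_type Base population type: `"F2"`, `"BC1"` or `"rBC1"`.
#' @param n_base Base population size (kept through cycles when
#'   `top_k * (top_k - 1) / 2 * n_dh` equals it).
#' @param genome A [sim_genome()].
#' @param density_cM_per_qtl,ratio_P QTL architecture, passed to
#'   [sample_qtl_model()].
#' @param methods Character vector from `c("GS", "OSGS")`.
#' @param omega OSGS weight on the primary-component rank.
#' @param top_k Lines selected per cycle.
#' @param n_dh Double haploids per cross.
#' @param n_cycles Number of selection cycles (0 = base statistics only).
#' @param n_self Selfing generations before cycle 0.
#' @param n_reps Number of independent replicates.
#' @param seed Master seed; `NULL` leaves the RNG state alone.
#' @param retrain Re-estimate marker effects from new phenotypes each
#'   cycle instead of reusing the cycle-0 effects (off by default, as in
#'   the study design).
#' @return A tibble of class `osgs_metrics` with columns `rep`, `cycle`,
#'   `method`, `omega`, `mu_BV`, `mu_P`, `mu_S`, `mu_EBV`: mean true
#'   breeding value, mean favorable primary/secondary allele proportions
#'   and mean estimated breeding value of the population at each cycle.
#' @seealso [metric_deltas()], [method_contrasts()]
#' @export
run_recurrent_selection <- function(pop_type = c("F2", "BC1", "rBC1"),
                                    n_base = 200,
                                    genome = sim_genome(),
                                    density_cM_per_qtl = 2,
                                    ratio_P = 0.6,
                                    methods = "GS",
                                    omega = 0.5,
                                    top_k = 5,
                                    n_dh = 20,
                                    n_cycles = 5,
                                    n_self = 4,
                                    n_reps = 1,
                                    seed = NULL,
                                    retrain = FALSE) {
  pop_type <- match.arg(pop_type)
  if (!all(methods %in% c("GS", "OSGS"))) abort("methods must be 'GS' and/or 'OSGS'")
  if (top_k > n_base) abort("top_k exceeds the base population size")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)

  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    qtl <- sample_qtl_model(genome, density_cM_per_qtl, ratio_P)
    base <- self_generations(found_population(pop_type, n_base, genome), n_self)
    pheno <- sim_phenotype(base, qtl)
    fit <- fit_ridge_blup(genotypes(base), pheno$y)
    part <- partition_effects(fit, "higher")
    method_seeds <- sample.int(.Machine$integer.max - 1, length(methods))

    rows <- vector("list", length(methods))
    for (k in seq_along(methods)) {
      set.seed(method_seeds[k])
      method <- methods[k]
      om <- if (method == "OSGS") omega else NA_real_
      pop <- base
      mpart <- part
      cyc <- vector("list", n_cycles + 1)
      cyc[[1]] <- dplyr::bind_cols(
        tibble::tibble(rep = r, cycle = 0L, method = method, omega = om),
        pop_metrics(pop, qtl, mpart)
      )
      for (cycle in seq_len(n_cycles)) {
        pop <- select_and_advance(pop, mpart, method, omega, top_k, n_dh, cycle)
        if (retrain) {
          ph <- sim_phenotype(pop, qtl)
          mpart <- partition_effects(fit_ridge_blup(genotypes(pop), ph$y), "higher")
        }
        cyc[[cycle + 1]] <- dplyr::bind_cols(
          tibble::tibble(rep = r, cycle = cycle, method = method, omega = om),
          pop_metrics(pop, qtl, mpart)
        )
      }
      rows[[k]] <- dplyr::bind_rows(cyc)
    }
    res[[r]] <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "seed") <- seed
  attr(out, "rep_seeds") <- rep_seeds
  class(out) <- c("osgs_metrics", class(out))
  out
}

guarded_ratio <- function(num, denom, eps = 1e-6) {
  ifelse(abs(denom) < eps, num, num / denom)
}

#' Per-cycle fold changes and normalized gains
#'
#' For each replicate and method, computes the outcome deltas relative to
#' cycle 0: `delta_BV = (mu_BV - mu_BV0) / mu_BV0`,
#' `delta_P = mu_P / mu_P0` and `delta_S = mu_S / mu_S0`. When the cycle-0
#' mean breeding value is numerically zero (an F2 base has expectation 0)
#' the unnormalized difference is reported instead and flagged in
#' `bv_normalized`.
#'
#' @param metrics A [run_recurrent_selection()] result.
#' @return A tibble with the input columns plus `delta_BV`, `delta_P`,
#'   `delta_S` and `bv_normalized`.
#' @export
metric_deltas <- function(metrics) {
  base <- dplyr::filter(metrics, .data$cycle == 0)
  base <- dplyr::select(base, "rep", "method",
                        mu_BV0 = "mu_BV", mu_P0 = "mu_P", mu_S0 = "mu_S")
  out <- dplyr::left_join(tibble::as_tibble(metrics), base, by = c("rep", "method"))
  dplyr::mutate(out,
    bv_normalized = abs(.data$mu_BV0) >= 1e-6,
    delta_BV = guarded_ratio(.data$mu_BV - .data$mu_BV0, .data$mu_BV0),
    delta_P = .data$mu_P / .data$mu_P0,
    delta_S = .data$mu_S / .data$mu_S0,
    mu_BV0 = NULL, mu_P0 = NULL, mu_S0 = NULL
  )
}

#' OSGS-versus-GS contrasts
#'
#' Paired contrasts between the two methods at each cycle, normalized by
#' the pre-selection (cycle-0) means:
#' `delta_EBV = (mu_EBV_OSGS - mu_EBV_GS) / mu_EBV0`, and analogously
#' `delta_P` and `delta_S` with their own cycle-0 denominators. Requires a
#' metrics table containing both methods (run with
#' `methods = c("GS", "OSGS")`).
#'
#' @param metrics A [run_recurrent_selection()] result with both methods.
#' @return A tibble with columns `rep`, `cycle`, `omega`, `delta_EBV`,
#'   `delta_P`, `delta_S`.
#' @export
method_contrasts <- function(metrics) {
  if (!all(c("GS", "OSGS") %in% metrics$method)) {
    abort("contrasts need metrics for both GS and OSGS")
  }
  om <- unique(metrics$omega[metrics$method == "OSGS"])
  gs <- dplyr::filter(metrics, .data$method == "GS")
  os <- dplyr::filter(metrics, .data$method == "OSGS")
  base <- dplyr::filter(gs, .data$cycle == 0)
  base <- dplyr::select(base, "rep", mu_EBV0 = "mu_EBV", mu_P0 = "mu_P", mu_S0 = "mu_S")
  j <- dplyr::left_join(
    dplyr::select(gs, "rep", "cycle", gs_EBV = "mu_EBV", gs_P = "mu_P", gs_S = "mu_S"),
    dplyr::select(os, "rep", "cycle", os_EBV = "mu_EBV", os_P = "mu_P", os_S = "mu_S"),
    by = c("rep", "cycle")
  )
  j <- dplyr::left_join(j, base, by = "rep")
  dplyr::transmute(j,
    rep = .data$rep, cycle = .data$cycle, omega = om[1],
    delta_EBV = guarded_ratio(.data$os_EBV - .data$gs_EBV, .data$mu_EBV0),
    delta_P = guarded_ratio(.data$os_P - .data$gs_P, .data$mu_P0),
    delta_S = guarded_ratio(.data$os_S - .data$gs_S, .data$mu_S0)
  )
}

#' One generation of family-wise GS/OSGS selection
#'
#' Applies the nested-association-mapping style selection scheme to a list
#' of families: within each family, select the top `top_k` lines under GS
#' and under OSGS at weight `omega`, cross each selected set in a half
#' diallel, derive `n_dh` double haploids per cross, and contrast the two
#' progeny populations. Favorable-allele proportions are computed from the
#' family's marker partition (favorable dosage averaged over all markers),
#' and the contrasts are normalized by the pre-selection family means:
#' `delta_EBV = (mu_EBV_OSGS - mu_EBV_GS) / mu_EBV_0`, likewise `delta_P`
#' and `delta_S`. Families with fewer than `top_k` lines are skipped with
#' a warning.
#'
#' @param families Named list; each element a list with `pop` (a
#'   `sim_pop`) and `partition` (an [partition_effects()] result for that
#'   family).
#' @param omega OSGS weight on the primary-component rank.
#' @param top_k Lines selected per family (4 crossed into 6 crosses by
#'   default).
#' @param n_dh Double haploids per cross (default 10, so 60 progeny per
#'   family at `top_k = 4`).
#' @return A tibble with one row per family: pre-selection means, per-
#'   method progeny means, and `delta_EBV`, `delta_P`, `delta_S`.
#' @export
nam_style_selection <- function(families, omega = 0.5, top_k = 4, n_dh = 10) {
  nm <- names(families) %||% paste0("family", seq_along(families))
  rows <- vector("list", length(families))
  for (i in seq_along(families)) {
    fam <- families[[i]]
    pop <- fam$pop
    part <- fam$partition
    if (n_lines(pop) < top_k) {
      warn(paste0("family '", nm[i], "' has fewer than ", top_k, " lines; skipped"))
      next
    }
    base_pr <- favorable_proportions(pop, part)
    base_ebv <- mean(drop(genotypes(pop) %*% part$effect))
    progeny <- function(method) {
      newpop <- select_and_advance(pop, part, method, omega, top_k, n_dh, cycle = 1)
      pr <- favorable_proportions(newpop, part)
      c(ebv = mean(drop(genotypes(newpop) %*% part$effect)),
        P = mean(pr$P), S = mean(pr$S))
    }
    gs <- progeny("GS")
    os <- progeny("OSGS")
    rows[[i]] <- tibble::tibble(
      family = nm[i], omega = omega, n_lines = n_lines(pop),
      mu_EBV_0 = base_ebv, mu_P_0 = mean(base_pr$P), mu_S_0 = mean(base_pr$S),
      mu_EBV_GS = gs[["ebv"]], mu_P_GS = gs[["P"]], mu_S_GS = gs[["S"]],
      mu_EBV_OSGS = os[["ebv"]], mu_P_OSGS = os[["P"]], mu_S_OSGS = os[["S"]],
      delta_EBV = guarded_ratio(os[["ebv"]] - gs[["ebv"]], base_ebv),
      delta_P = guarded_ratio(os[["P"]] - gs[["P"]], mean(base_pr$P)),
      delta_S = guarded_ratio(os[["S"]] - gs[["S"]], mean(base_pr$S))
    )
  }
  dplyr::bind_rows(rows)
}
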