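# Ridge-regression BLUP of marker effects and its partition by parental
# origin of the favorable allele.
#
# Model: y = X b + W u + e,  u ~ N(0, I sigma2_u),  e ~ N(0, I sigma2_e).
# With K = W W' the restricted likelihood depends on lambda = sigma2_e /
# sigma2_u only through the spectrum of S K S (S the projection removing X),
# so REML reduces to one eigendecomposition plus a 1-D search in log(lambda).

match_trait <- function(y, lines) {
  if (is.data.frame(y)) {
    y <- as.data.frame(y)
    if (!"line" %in% names(y) || ncol(y) < 2) {
      abort("trait data frame must have a 'line' column and one value column")
    }
    val <- setdiff(names(y), "line")[1]
    idx <- match(lines, as.character(y$line))
    if (anyNA(idx)) abort("trait values missing for some lines")
    return(as.numeric(y[[val]][idx]))
  }
  as.numeric(y)
}

#' Fit the ridge-regression BLUP of marker effects
#'
#' Fits `y = Xb + Wu + e` with `u ~ N(0, I * sigma2_u)` and
#' `e ~ N(0, I * sigma2_e)` on origin-coded genotypes `W`. The variance
#' components are estimated by REML on the spectral decomposition of the
#' genomic kernel `WW'` (one symmetric eigendecomposition of the
#' fixed-effect-projected kernel, then a one-dimensional optimization of the
#' restricted likelihood in `log(lambda)` with `lambda = sigma2_e/sigma2_u`).
#' Marker effects are the kernel-form BLUP
#' `u_hat = W'(WW' + lambda I)^-1 (y - X b_hat)`, with `b_hat` the
#' generalized-least-squares estimate; by the Woodbury identity this equals
#' the penalized normal-equation ridge solution
#' `(W'W + lambda I)^-1 W'(y - X b_hat)`.
#'
#' Variance components are floored at `1e-8 * var(y)` so that `lambda`
#' stays finite on degenerate data; a trait with no residual variation
#' after the fixed effects yields a zero effect vector.
#'
#' @param geno Origin-coded genotypes: data frame with a `line` column or a
#'   numeric matrix (lines x markers). No missing values; fractional imputed
#'   entries are allowed.
#' @param y Trait values: numeric vector in row order of `geno`, or a data
#'   frame with columns `line` and one value column.
#' @param X Fixed-effect design matrix (default intercept only). Must have
#'   full column rank.
#' @param lambda Optional fixed ridge parameter; when supplied the REML step
#'   is skipped and `sigma2_u`, `sigma2_e` are profiled at that ratio.
#' @return An object of class `ridge_blup` with elements `u_hat` (named
#'   marker effects), `b_hat`, `sigma2_u`, `sigma2_e`, `lambda`, `h2`
#'   (kernel-scaled heritability), `y_adj` (`y - X b_hat`), `loglik`
#'   (restricted log-likelihood, up to a constant), `lines`, `markers`.
#'   Use [tidy()] for a per-marker tibble and [glance()] for a one-row
#'   model summary.
#' @export
#' @examples
#' W <- matrix(sample(c(-1, 1), 60, TRUE), nrow = 6)
#' y <- rnorm(6)
#' fit <- fit_ridge_blup(W, y)
#' glance(fit)
fit_ridge_blup <- function(geno, y, X = NULL, lambda = NULL) {
  W <- as_geno_matrix(geno)
  if (anyNA(W)) abort("genotypes contain missing values; impute first")
  n <- nrow(W)
  m <- ncol(W)
  if (n < 3) abort("need at least 3 lines to fit the mixed model")
  y <- match_trait(y, rownames(W))
  if (length(y) != n) abort("length of y does not match number of lines")
  if (!all(is.finite(y))) abort("non-finite trait values")

  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  q <- ncol(X)
  if (qr(X)$rank < q) abort("fixed-effect design X is rank deficient")
  if (n - q < 2) abort("too few residual degrees of freedom")

  K <- tcrossprod(W)
  XtXi <- solve(crossprod(X))
  S <- diag(n) - X %*% XtXi %*% t(X)
  M <- S %*% K %*% S
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  keep <- seq_len(n - q)
  xi <- pmax(ee$values[keep], 0)
  U <- ee$vectors[, keep, drop = FALSE]
  if (max(xi) <= 1e-10 * max(1, mean(diag(K)))) {
    abort("degenerate genomic kernel: lines are genomically identical")
  }
  eta2 <- drop(crossprod(U, y))^2

  floor_v <- 1e-8 * max(var(y), .Machine$double.eps)
  nq <- n - q

  if (sum(eta2) <= 1e-28 * max(1, sum(y^2))) {
    # no variation left after the fixed effects: zero genetic signal
    lambda_hat <- if (is.null(lambda)) 1 else lambda
    s2u <- floor_v
    s2e <- floor_v
    b_hat <- drop(XtXi %*% crossprod(X, y))
    u_hat <- rep(0, m)
    ll <- NA_real_
  } else {
    rll <- function(log_lambda) {
      lam <- exp(log_lambda)
      s2 <- sum(eta2 / (xi + lam)) / nq
      -0.5 * (nq * (log(2 * pi * s2) + 1) + sum(log(xi + lam)))
    }
    if (is.null(lambda)) {
      opt <- optimize(rll, interval = c(log(1e-9), log(1e9)), maximum = TRUE)
      lambda_hat <- exp(opt$maximum)
      ll <- opt$objective
    } else {
      if (lambda <= 0) abort("lambda must be positive")
      lambda_hat <- lambda
      ll <- rll(log(lambda))
    }
    s2u <- max(sum(eta2 / (xi + lambda_hat)) / nq, floor_v)
    s2e <- max(lambda_hat * s2u, floor_v)
    lambda_hat <- s2e / s2u
    Hi <- chol2inv(chol(K + lambda_hat * diag(n)))
    XtHiX <- crossprod(X, Hi %*% X)
    b_hat <- drop(solve(XtHiX, crossprod(X, Hi %*% y)))
    u_hat <- drop(crossprod(W, Hi %*% (y - X %*% b_hat)))
  }

  names(b_hat) <- colnames(X)
  names(u_hat) <- colnames(W) %||% paste0("M", seq_len(m))
  y_adj <- drop(y - X %*% b_hat)
  mean_xi <- mean(xi)
  structure(list(
    u_hat = u_hat, b_hat = b_hat,
    sigma2_u = s2u, sigma2_e = s2e, lambda = lambda_hat,
    h2 = s2u * mean_xi / (s2u * mean_xi + s2e),
    y_adj = setNames(y_adj, rownames(W)),
    loglik = ll,
    reml = is.null(lambda),
    lines = rownames(W), markers = names(u_hat),
    n = n, m = m
  ), class = "ridge_blup")
}

#' @export
print.ridge_blup <- function(x, ...) {
  cat("Ridge-regression BLUP of marker effects\n")
  cat("  lines:", x$n, "  markers:", x$m, "\n")
  cat(sprintf("  sigma2_u = %.4g  sigma2_e = %.4g  lambda = %.4g  h2 = %.3f\n",
              x$sigma2_u, x$sigma2_e, x$lambda, x$h2))
  invisible(x)
}

#' @rdname fit_ridge_blup
#' @param x A `ridge_blup` object.
#' @param ... Unused.
#' @method tidy ridge_blup
#' @export
tidy.ridge_blup <- function(x, ...) {
  tibble::tibble(marker = x$markers, effect = unname(x$u_hat))
}

#' @rdname fit_ridge_blup
#' @method glance ridge_blup
#' @export
glance.ridge_blup <- function(x, ...) {
  tibble::tibble(
    n_lines = x$n, n_markers = x$m,
    sigma2_u = x$sigma2_u, sigma2_e = x$sigma2_e,
    lambda = x$lambda, h2 = x$h2,
    loglik = x$loglik, reml = x$reml
  )
}

effects_from <- function(estimate) {
  if (inherits(estimate, "ridge_blup")) {
    return(tibble::tibble(marker = estimate$markers, effect = unname(estimate$u_hat)))
  }
  if (is.data.frame(estimate)) {
    if (!all(c("marker", "effect") %in% names(estimate))) {
      abort("effect table must have columns 'marker' and 'effect'")
    }
    return(tibble::tibble(marker = as.character(estimate$marker),
                          effect = as.numeric(estimate$effect)))
  }
  if (is.numeric(estimate)) {
    nm <- names(estimate) %||% paste0("M", seq_along(estimate))
    return(tibble::tibble(marker = nm, effect = unname(estimate)))
  }
  abort("cannot interpret 'estimate' as marker effects")
}

#' Partition marker effects by parental origin of the favorable allele
#'
#' Under origin coding (primary parent = -1) and a trait whose favorable
#' direction is "higher", a negative coefficient means the trait-increasing
#' allele is carried by the primary parent (class `P`) and a positive
#' coefficient means it is carried by the secondary parent (class `S`);
#' with `favorable_direction = "lower"` the classes swap. Coefficients that
#' are exactly zero form their own class `Z` and contribute to neither
#' component. The split vectors satisfy `u1 + u2 = effect` elementwise.
#'
#' @param estimate A [fit_ridge_blup()] object, a data frame with columns
#'   `marker` and `effect`, or a named numeric vector.
#' @param favorable_direction `"higher"` (default) if larger trait values
#'   are favorable, `"lower"` otherwise.
#' @return A tibble of class `effect_partition` with columns `marker`,
#'   `effect`, `class` (`P`/`S`/`Z`), `u1` (effect where class is `P`, else
#'   0) and `u2` (effect where class is `S`, else 0); the favorable
#'   direction is stored as an attribute.
#' @export
partition_effects <- function(estimate, favorable_direction = c("higher", "lower")) {
  favorable_direction <- match.arg(favorable_direction)
  eff <- effects_from(estimate)
  u <- eff$effect
  cls <- rep("Z", length(u))
  if (favorable_direction == "higher") {
    cls[u < 0] <- "P"
    cls[u > 0] <- "S"
  } else {
    cls[u > 0] <- "P"
    cls[u < 0] <- "S"
  }
  out <- tibble::tibble(
    marker = eff$marker, effect = u, class = cls,
    u1 = ifelse(cls == "P", u, 0),
    u2 = ifelse(cls == "S", u, 0)
  )
  attr(out, "favorable_direction") <- favorable_direction
  class(out) <- c("effect_partition", class(out))
  out
}

favorable_direction_of <- function(x) {
  attr(x, "favorable_direction") %||% "higher"
}

#' Predict total and origin-specific breeding values
#'
#' Computes `a_hat = W u`, `a1_hat = W u1` and `a2_hat = W u2`, so that
#' `a_hat = a1_hat + a2_hat` for every line. `a1_hat` is the contribution of
#' markers whose favorable allele comes from the primary parent and
#' `a2_hat` the secondary-parent analogue; both are signed so that larger
#' values mean more favorable content when the favorable direction is
#' "higher" (and the reverse when "lower").
#'
#' @param geno Origin-coded genotypes (data frame with `line` column, or
#'   matrix) whose marker columns match the partition's markers in order.
#' @param partition An [partition_effects()] result.
#' @return A tibble of class `breeding_values` with columns `line`,
#'   `a_hat`, `a1_hat`, `a2_hat`.
#' @export
predict_breeding_values <- function(geno, partition) {
  W <- as_geno_matrix(geno)
  if (anyNA(W)) abort("genotypes contain missing values; impute first")
  if (ncol(W) != nrow(partition)) {
    abort("genotypes and partition have different marker counts")
  }
  if (!is.null(colnames(W)) && !identical(colnames(W), partition$marker)) {
    abort("genotype markers do not match the partition's markers (same set and order required)")
  }
  out <- tibble::tibble(
    line = rownames(W),
    a_hat = unname(drop(W %*% partition$effect)),
    a1_hat = unname(drop(W %*% partition$u1)),
    a2_hat = unname(drop(W %*% partition$u2))
  )
  attr(out, "favorable_direction") <- favorable_direction_of(partition)
  class(out) <- c("breeding_values", class(out))
  out
}

#' Expected correlations of the breeding value with its components
#'
#' For unlinked markers with equal genotype variance (the idealization of a
#' set of independent inbred genotypes at frequency one half), the expected
#' correlation between the total breeding value and its primary-parent
#' component is `sqrt(sum(u_P^2) / sum(u^2))`, and analogously for the
#' secondary component. When no effect is exactly zero the two squared
#' correlations sum to one.
#'
#' @param partition An [partition_effects()] result.
#' @return A one-row tibble with columns `rho1` and `rho2`.
#' @export
expected_component_correlations <- function(partition) {
  tot <- sum(partition$effect^2)
  if (tot == 0) abort("all marker effects are zero; correlations undefined")
  tibble::tibble(
    rho1 = sqrt(sum(partition$u1^2) / tot),
    rho2 = sqrt(sum(partition$u2^2) / tot)
  )
}

#' Prediction accuracies of total and origin-specific breeding values
#'
#' Pearson correlations between the fixed-effect-adjusted trait
#' (`y - X b_hat`) and each of `a_hat`, `a1_hat`, `a2_hat`.
#'
#' @param bv A [predict_breeding_values()] result.
#' @param y_adj Adjusted trait values: numeric vector in line order, or a
#'   `ridge_blup` fit (its stored `y_adj` is used).
#' @return A one-row tibble with columns `r_A`, `r_P`, `r_S`. A zero-variance
#'   argument yields `NaN` with a warning.
#' @export
prediction_accuracy <- function(bv, y_adj) {
  if (inherits(y_adj, "ridge_blup")) y_adj <- y_adj$y_adj
  y_adj <- as.numeric(y_adj)
  if (length(y_adj) != nrow(bv)) abort("y_adj length does not match lines")
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(NaN)
    cor(a, b)
  }
  out <- tibble::tibble(
    r_A = safe_cor(y_adj, bv$a_hat),
    r_P = safe_cor(y_adj, bv$a1_hat),
    r_S = safe_cor(y_adj, bv$a2_hat)
  )
  if (anyNA(out)) warn("zero variance: correlation undefined (NaN)")
  out
}

#' Compare the primary and secondary absolute-effect distributions
#'
#' Two-sample Kolmogorov-Smirnov comparison of `|effect|` between the `P`
#' and `S` marker classes, as a measure of how differently the two parents
#' contribute favorable effects. The asymptotic two-sided p-value uses the
#' Kolmogorov distribution at effective size `nP * nS / (nP + nS)`.
#'
#' @param partition An [partition_effects()] result with at least one `P`
#'   and one `S` marker.
#' @param bonferroni_n Optional number of families tested in parallel; when
#'   given, the output gains a `significant` column comparing `p_value`
#'   against `0.05 / bonferroni_n`.
#' @return A one-row tibble with columns `n_P`, `n_S`, `D`, `p_value` and
#'   `neglog10_p`.
#' @export
ks_compare_effects <- function(partition, bonferroni_n = NULL) {
  xp <- abs(partition$effect[partition$class == "P"])
  xs <- abs(partition$effect[partition$class == "S"])
  if (!length(xp) || !length(xs)) {
    abort("one parent contributes no favorable alleles; the comparison needs both classes")
  }
  kt <- suppressWarnings(stats::ks.test(xp, xs, exact = FALSE))
  out <- tibble::tibble(
    n_P = length(xp), n_S = length(xs),
    D = unname(kt$statistic),
    p_value = kt$p.value,
    neglog10_p = -log10(kt$p.value)
  )
  if (!is.null(bonferroni_n)) {
    out$significant <- out$p_value < 0.05 / bonferroni_n
  }
  out
}
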