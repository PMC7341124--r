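# Origin coding of bi-parental marker data:
#   -1 = homozygous for the primary-parent allele
#    0 = heterozygous
#   +1 = homozygous for the secondary-parent allele
# Imputed entries may be fractional, so downstream code never assumes
# integer genotypes.

IUPAC_HET <- list(
  W = c("A", "T"), K = c("G", "T"), R = c("A", "G"),
  S = c("C", "G"), Y = c("C", "T"), M = c("A", "C")
)
IUPAC_VALID <- c("A", "C", "G", "T", "N", names(IUPAC_HET))

#' Validate a genetic map
#'
#' A genetic map relates each marker to a chromosome and a genetic position
#' in centimorgan. Markers are returned sorted by `(chromosome, cM)`; two
#' markers of the same chromosome at exactly the same position are rejected
#' because the flanking-imputation rule needs an unambiguous marker order.
#'
#' @param map A data frame with columns `marker`, `chromosome` and `cM`
#'   (additional columns are kept).
#' @return A tibble sorted by `(chromosome, cM)`.
#' @export
#' @examples
#' genetic_map(data.frame(marker = c("m2", "m1"), chromosome = 1, cM = c(7.5, 2)))
genetic_map <- function(map) {
  map <- tibble::as_tibble(map)
  need <- c("marker", "chromosome", "cM")
  if (!all(need %in% names(map))) {
    abort(paste0("map must have columns ", paste(need, collapse = ", ")))
  }
  if (anyNA(map[need])) abort("map contains missing values")
  if (any(map$chromosome < 1) || any(map$chromosome != round(map$chromosome))) {
    abort("chromosome must be a positive integer")
  }
  if (any(map$cM < 0)) abort("cM positions must be non-negative")
  if (anyDuplicated(map$marker)) abort("duplicated marker ids in map")
  map <- dplyr::arrange(map, .data$chromosome, .data$cM)
  ties <- dplyr::group_by(map, .data$chromosome)
  ties <- dplyr::summarise(ties, tie = anyDuplicated(.data$cM) > 0)
  if (any(ties$tie)) {
    abort("two markers at identical cM position on one chromosome; positions must be distinct")
  }
  map
}

# Coerce a lines-by-markers table (tibble with a `line` first column, or a
# matrix with rownames) to a numeric matrix with line rownames.
as_geno_matrix <- function(geno) {
  if (is.matrix(geno)) {
    storage.mode(geno) <- "double"
    if (is.null(rownames(geno))) rownames(geno) <- paste0("L", seq_len(nrow(geno)))
    return(geno)
  }
  geno <- as.data.frame(geno)
  id_col <- if ("line" %in% names(geno)) "line" else names(geno)[1]
  lines <- as.character(geno[[id_col]])
  W <- as.matrix(geno[setdiff(names(geno), id_col)])
  storage.mode(W) <- "double"
  rownames(W) <- lines
  W
}

geno_as_tibble <- function(W) {
  out <- tibble::as_tibble(as.data.frame(W))
  dplyr::bind_cols(tibble::tibble(line = rownames(W)), out)
}

parent_calls <- function(x, markers, who) {
  if (is.data.frame(x)) {
    x <- as.data.frame(x)
    if ("line" %in% names(x)) x <- x[setdiff(names(x), "line")]
    if (nrow(x) != 1) abort(paste0(who, " genotype table must have exactly one row"))
    x <- unlist(x[1, , drop = TRUE])
  }
  if (is.null(names(x))) abort(paste0(who, " genotypes must be named by marker"))
  x <- setNames(toupper(as.character(x)), names(x))
  missing <- setdiff(markers, names(x))
  if (length(missing)) {
    abort(paste0(who, " genotype missing for marker(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  x[markers]
}

#' Recode IUPAC genotype calls to origin coding
#'
#' Converts raw SNP calls of a bi-parental population into the origin coding
#' used throughout the package: lines matching the primary (elite) parent's
#' homozygous call become -1, lines matching the secondary (donor/exotic)
#' parent become +1, and heterozygous ambiguity codes consistent with both
#' parental alleles become 0. Calls that are `N`, inconsistent with either
#' parent, or at markers monomorphic between the two parents are set to `NA`
#' and are expected to be filled by [impute_flanking()]. Markers at which a
#' parent itself carries a heterozygous code are dropped with a warning.
#'
#' @param geno Data frame of raw calls: first column `line`, remaining
#'   columns one per marker, values IUPAC symbols (`A`, `C`, `G`, `T`, `N`
#'   and the two-allele codes `W`, `K`, `R`, `S`, `Y`, `M`).
#' @param primary,secondary Named character vectors (or one-row data frames)
#'   of the parental calls, named by marker.
#' @return A tibble of the same shape with numeric values in
#'   \{-1, 0, 1, NA\}. Swapping `primary` and `secondary` negates every
#'   non-missing value.
#' @seealso [impute_flanking()]
#' @export
recode_biparental <- function(geno, primary, secondary) {
  geno <- tibble::as_tibble(geno)
  id_col <- if ("line" %in% names(geno)) "line" else names(geno)[1]
  markers <- setdiff(names(geno), id_col)
  lines <- as.character(geno[[id_col]])

  p <- parent_calls(primary, markers, "primary")
  s <- parent_calls(secondary, markers, "secondary")

  het_parent <- markers[p %in% names(IUPAC_HET) | s %in% names(IUPAC_HET)]
  if (length(het_parent)) {
    warn(paste0("dropping ", length(het_parent),
                " marker(s) with a heterozygous parent call: ",
                paste(head(het_parent, 5), collapse = ", ")))
    markers <- setdiff(markers, het_parent)
  }
  bad_parent <- markers[!(p[markers] %in% c("A", "C", "G", "T")) |
                        !(s[markers] %in% c("A", "C", "G", "T"))]
  if (length(bad_parent)) {
    abort(paste0("parent call is not a valid homozygous base at marker(s): ",
                 paste(head(bad_parent, 5), collapse = ", ")))
  }

  out <- matrix(NA_real_, nrow = length(lines), ncol = length(markers),
                dimnames = list(lines, markers))
  for (m in markers) {
    calls <- toupper(as.character(geno[[m]]))
    bad <- !(calls %in% IUPAC_VALID) & !is.na(calls)
    if (any(bad)) {
      j <- which(bad)[1]
      abort(paste0("unknown genotype symbol '", calls[j], "' for line '",
                   lines[j], "' at marker '", m, "'"))
    }
    if (p[[m]] == s[[m]]) next  # monomorphic between parents -> all missing
    v <- rep(NA_real_, length(calls))
    v[calls == p[[m]]] <- -1
    v[calls == s[[m]]] <- 1
    het <- names(IUPAC_HET)[vapply(IUPAC_HET, function(a) setequal(a, c(p[[m]], s[[m]])), logical(1))]
    if (length(het)) v[calls == het] <- 0
    out[, m] <- v
  }
  geno_as_tibble(out)
}

# Fill NA runs in one within-chromosome vector: interior entries take the
# mean of the nearest non-missing value on each side; leading/trailing runs
# copy the single nearest value; an all-missing vector becomes 0.
fill_flanking <- function(v) {
  nas <- which(is.na(v))
  if (!length(nas)) return(v)
  obs <- which(!is.na(v))
  if (!length(obs)) return(rep(0, length(v)))
  k <- findInterval(nas, obs)
  left <- ifelse(k >= 1L, v[obs[pmax(k, 1L)]], NA_real_)
  right <- ifelse(k < length(obs), v[obs[pmin(k + 1L, length(obs))]], NA_real_)
  v[nas] <- rowMeans(cbind(left, right), na.rm = TRUE)
  v
}

#' Impute missing origin-coded genotypes from flanking markers
#'
#' Each missing entry is replaced by the arithmetic mean of the nearest
#' non-missing marker value to its left and right on the same chromosome
#' (nearest in map order). Missing runs at a chromosome start or end copy
#' the single nearest non-missing value. A line missing an entire
#' chromosome is set to 0, the uninformative midpoint, with a message.
#' Imputed values may be fractional and are used as-is in prediction.
#' The operation is idempotent.
#'
#' @param geno Data frame (first column `line`) or matrix of origin-coded
#'   genotypes with `NA` for missing entries.
#' @param map A [genetic_map()] covering every marker column of `geno`.
#' @return A tibble with no missing values, markers ordered as in the map.
#' @export
impute_flanking <- function(geno, map) {
  map <- genetic_map(map)
  W <- as_geno_matrix(geno)
  missing_map <- setdiff(colnames(W), map$marker)
  if (length(missing_map)) {
    abort(paste0("marker(s) absent from map: ", paste(head(missing_map, 5), collapse = ", ")))
  }
  map <- map[map$marker %in% colnames(W), ]
  W <- W[, map$marker, drop = FALSE]
  n_empty <- 0L
  for (chr in unique(map$chromosome)) {
    cols <- which(map$chromosome == chr)
    block <- W[, cols, drop = FALSE]
    if (anyNA(block)) {
      for (i in seq_len(nrow(block))) {
        if (anyNA(block[i, ])) {
          if (all(is.na(block[i, ]))) n_empty <- n_empty + 1L
          block[i, ] <- fill_flanking(block[i, ])
        }
      }
      W[, cols] <- block
    }
  }
  if (n_empty > 0L) {
    inform(paste0(n_empty, " line-chromosome(s) with no observed marker imputed to 0"))
  }
  geno_as_tibble(W)
}
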