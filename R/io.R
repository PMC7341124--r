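# Table readers/writers and the worked-example fixture.

NA_TOKENS <- c("NA", "", ".")

normalize_minus <- function(df) {
  chr <- vapply(df, is.character, logical(1))
  df[chr] <- lapply(df[chr], function(x) gsub("−", "-", x))
  df
}

read_any_delim <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, na = NA_TOKENS,
                          show_col_types = FALSE, trim_ws = TRUE,
                          col_types = readr::cols(.default = readr::col_character()))
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    abort(paste0("malformed table ", path, ": row ", pr$row[1], ", column ",
                 pr$col[1], " (", pr$expected[1], " expected, got ", pr$actual[1], ")"))
  }
  normalize_minus(tibble::as_tibble(df))
}

retype_numeric <- function(df, keep = character(0), strict = TRUE) {
  for (nm in setdiff(names(df), keep)) {
    suppressWarnings(v <- as.numeric(df[[nm]]))
    bad <- is.na(v) & !is.na(df[[nm]])
    if (any(bad)) {
      if (!strict) next  # leave genuinely non-numeric columns (e.g. grouping) alone
      abort(paste0("non-numeric value '", df[[nm]][which(bad)[1]], "' in column '",
                   nm, "', row ", which(bad)[1]))
    }
    df[[nm]] <- v
  }
  df
}

#' Read a lines-by-markers genotype table
#'
#' Reads a CSV/TSV genotype table (delimiter from the file extension,
#' overridable), with lines as rows, a header row of marker ids and the
#' line id in the first column. Values may be IUPAC symbols or numeric
#' origin codes; the coding is auto-detected unless forced. `NA`, empty
#' strings and `.` are treated as missing, and the Unicode minus sign is
#' accepted on input.
#'
#' @param path File path.
#' @param coding `"auto"` (default), `"iupac"` or `"numeric"`.
#' @param delim Field delimiter; default `","` or `"\t"` by extension.
#' @param transpose Set `TRUE` for markers-as-rows files.
#' @return A tibble with column `line` followed by one column per marker
#'   (character for IUPAC, numeric in `[-1, 1]` otherwise).
#' @export
read_geno_table <- function(path, coding = c("auto", "iupac", "numeric"),
                            delim = NULL, transpose = FALSE) {
  coding <- match.arg(coding)
  df <- read_any_delim(path, delim)
  if (transpose) {
    ids <- df[[1]]
    mat <- t(as.matrix(df[-1]))
    df <- dplyr::bind_cols(tibble::tibble(line = colnames(df)[-1]),
                           tibble::as_tibble(as.data.frame(mat)))
    names(df) <- c("line", ids)
  }
  names(df)[1] <- "line"
  vals <- unlist(df[-1], use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (coding == "auto") {
    coding <- if (all(toupper(vals) %in% IUPAC_VALID)) "iupac" else "numeric"
  }
  if (coding == "iupac") {
    bad <- vals[!(toupper(vals) %in% IUPAC_VALID)]
    if (length(bad)) abort(paste0("invalid IUPAC symbol(s): ", paste(head(unique(bad), 5), collapse = ", ")))
    df[-1] <- lapply(df[-1], function(x) toupper(as.character(x)))
  } else {
    df <- retype_numeric(df, keep = "line")
    rng <- range(unlist(df[-1], use.names = FALSE), na.rm = TRUE)
    if (rng[1] < -1 || rng[2] > 1) {
      abort("numeric genotype values outside [-1, 1]; expected origin coding")
    }
  }
  inform(paste0("read ", nrow(df), " lines x ", ncol(df) - 1, " markers (", coding, ") from ", path))
  df
}

#' Read a genetic map file
#'
#' Three columns (marker, chromosome, cM), any header names; validated and
#' sorted by [genetic_map()].
#'
#' @inheritParams read_geno_table
#' @return A genetic map tibble.
#' @export
read_genetic_map <- function(path, delim = NULL) {
  df <- read_any_delim(path, delim)
  if (ncol(df) < 3) abort("map file needs 3 columns: marker, chromosome, cM")
  df <- df[1:3]
  names(df) <- c("marker", "chromosome", "cM")
  df <- retype_numeric(df, keep = "marker")
  genetic_map(df)
}

#' Read a per-line trait table
#'
#' First column is the line id; remaining columns are traits (coerced to
#' numeric) or grouping columns such as a family id (left as character).
#'
#' @inheritParams read_geno_table
#' @return A tibble with column `line` and one numeric column per trait.
#' @export
read_trait_table <- function(path, delim = NULL) {
  df <- read_any_delim(path, delim)
  names(df)[1] <- "line"
  retype_numeric(df, keep = "line", strict = FALSE)
}

#' The ten-marker worked example
#'
#' A small fully worked example of origin-specific partitioning: five
#' inbred lines scored at ten unlinked markers (origin coding, -1 =
#' elite/primary homozygote), the ten marker regression coefficients
#' (seven favorable alleles from the elite parent, three from the exotic
#' parent), and the resulting total, elite and exotic breeding values per
#' line. Used as the package's reference fixture.
#'
#' @return A list of three tibbles: `genotypes` (line x M1..M10),
#'   `effects` (`marker`, `effect`) and `breeding_values` (`line`,
#'   `a_hat`, `a1_hat`, `a2_hat`).
#' @export
#' @examples
#' ex <- table1_example()
#' part <- partition_effects(ex$effects, "higher")
#' predict_breeding_values(ex$genotypes, part)
table1_example <- function() {
  genotypes <- tibble::tibble(
    line = c("ID1", "ID2", "ID3", "ID4", "ID5"),
    M1 = c(-1, 1, 1, -1, 1),
    M2 = c(-1, -1, 1, -1, -1),
    M3 = c(-1, 1, -1, -1, 1),
    M4 = c(-1, -1, -1, -1, 1),
    M5 = c(1, 1, -1, -1, 1),
    M6 = c(1, -1, -1, 1, 1),
    M7 = c(-1, -1, 1, 1, -1),
    M8 = c(1, 1, 1, 1, -1),
    M9 = c(-1, -1, 1, 1, -1),
    M10 = c(1, 1, 1, -1, 1)
  )
  effects <- tibble::tibble(
    marker = paste0("M", 1:10),
    effect = c(-0.95, -0.34, -0.47, -0.11, -0.49, -0.63, -1.24, 0.22, 0.38, 0.82)
  )
  breeding_values <- tibble::tibble(
    line = genotypes$line,
    a_hat = c(2.65, 1.07, 0.59, 0.27, -0.85),
    a1_hat = c(1.99, 0.41, -0.83, 0.49, -1.07),
    a2_hat = c(0.66, 0.66, 1.42, -0.22, 0.22)
  )
  list(genotypes = genotypes, effects = effects, breeding_values = breeding_values)
}

#' Write the worked-example fixture to disk
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the three CSV files written
#'   (`table1_genotypes.csv`, `table1_effects.csv`,
#'   `table1_breeding_values.csv`).
#' @export
write_table1_example <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ex <- table1_example()
  paths <- file.path(dir, c("table1_genotypes.csv", "table1_effects.csv",
                            "table1_breeding_values.csv"))
  readr::write_csv(ex$genotypes, paths[1])
  readr::write_csv(ex$effects, paths[2])
  readr::write_csv(ex$breeding_values, paths[3])
  invisible(paths)
}

#' Write a JSON run manifest
#'
#' Records the configuration, master and per-replicate seeds, package
#' version and the md5 checksum of every output file, so a run can be
#' audited and reproduced.
#'
#' @param dir Output directory (created if needed).
#' @param config Named list echoing the run configuration.
#' @param seeds Named list or vector of seeds used.
#' @param files Character vector of output file paths.
#' @return Invisibly, the manifest path (`manifest.json` in `dir`).
#' @export
write_manifest <- function(dir, config, seeds, files) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    inform(paste0("created output directory ", dir))
  }
  manifest <- list(
    package = "osgs",
    version = as.character(utils::packageVersion("osgs")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = seeds,
    outputs = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
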