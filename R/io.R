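count_columns <- c("site_id", "gene_id", "site_class", "host_id", "A", "D")

#' Read a long-format allele count table
#'
#' Reads a tab-separated table of per-site, per-host alternate-allele read
#' counts and depths with columns `site_id`, `gene_id`, `site_class`,
#' `host_id`, `A`, `D` (one row per site-host pair) and validates it:
#' `A` and `D` must be nonnegative integers with `A <= D`, `site_class`
#' must be `synonymous` or `nonsynonymous`, and `(site_id, host_id)` pairs
#' must be unique. Violations are rejected with the offending row numbers,
#' never silently fixed.
#'
#' @param path path to a TSV file with a header row.
#' @return validated count data frame (possibly empty).
#' @export
read_count_table <- function(path) {
  if (!file.exists(path))
    stop_gp(paste0("file not found: ", path), "gammaprev_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  require_columns(df, count_columns, paste0("count table '", path, "'"))
  extra_sp <- intersect("species_id", names(df))
  df <- df[c(count_columns, extra_sp)]
  if (nrow(df) == 0L) {
    df$A <- integer(0); df$D <- integer(0)
    return(validate_count_matrix(df))
  }
  for (col in c("A", "D")) {
    suppressWarnings(num <- as.numeric(df[[col]]))
    bad <- is.na(num) | num != floor(num)
    if (any(bad))
      stop_gp(sprintf("non-integer '%s' value(s) at row(s): %s", col,
                      paste(utils::head(which(bad), 5), collapse = ", ")),
              "gammaprev_parse_error")
    df[[col]] <- as.integer(num)
  }
  validate_count_matrix(df)
}

#' @keywords internal
validate_count_matrix <- function(df) {
  require_columns(df, count_columns, "count table")
  if (nrow(df) == 0L) return(df)
  if (any(df$A < 0) || any(df$D < 0))
    stop_gp("'A' and 'D' must be nonnegative", "gammaprev_format_error")
  bad <- df$A > df$D
  if (any(bad))
    stop_gp(sprintf("A > D at row(s): %s",
                    paste(utils::head(which(bad), 5), collapse = ", ")),
            "gammaprev_format_error")
  bad_class <- !df$site_class %in% c("synonymous", "nonsynonymous")
  if (any(bad_class))
    stop_gp(sprintf("invalid site_class at row(s): %s",
                    paste(utils::head(which(bad_class), 5), collapse = ", ")),
            "gammaprev_format_error")
  dup <- duplicated(df[c("site_id", "host_id")])
  if (any(dup))
    stop_gp(sprintf("duplicated (site_id, host_id) at row(s): %s",
                    paste(utils::head(which(dup), 5), collapse = ", ")),
            "gammaprev_format_error")
  df
}

#' Write any long-format result table as TSV
#'
#' Tab-separated text with a header, no quoting, no row names; reading a
#' count table back with [read_count_table()] round-trips it exactly.
#'
#' @param records nonempty data frame (zero rows allowed, `NULL` not).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(records, path) {
  if (is.null(records) || !is.data.frame(records))
    stop_gp("'records' must be a data frame", "gammaprev_domain_error")
  ok <- try(suppressWarnings(
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop_gp(paste0("cannot write to: ", path), "gammaprev_io_error")
  invisible(path)
}

#' Read a detection-filtered frequency table
#'
#' TSV with columns `site_id`, `host_id`, `f`, `D` (extra columns kept).
#'
#' @param path path to a TSV file.
#' @return frequency data frame.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path))
    stop_gp(paste0("file not found: ", path), "gammaprev_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("site_id", "host_id", "f", "D"),
                  paste0("frequency table '", path, "'"))
  if (nrow(df) && (any(df$f < 0) || any(df$f > 1)))
    stop_gp("frequencies must lie in [0, 1]", "gammaprev_format_error")
  df
}

#' Read a per-host strain-structure table
#'
#' TSV with columns `species_id`, `host_id`, `has_strains` (0/1), the
#' output of an external strain-inference step (or the synthetic ground
#' truth).
#'
#' @param path path to a TSV file.
#' @return strain-structure data frame.
#' @export
read_strain_table <- function(path) {
  if (!file.exists(path))
    stop_gp(paste0("file not found: ", path), "gammaprev_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("species_id", "host_id", "has_strains"),
                  paste0("strain table '", path, "'"))
  if (nrow(df) && !all(df$has_strains %in% c(0L, 1L)))
    stop_gp("'has_strains' must be 0 or 1", "gammaprev_format_error")
  df
}

#' Convert a long frequency table to a wide site-by-host matrix
#'
#' Convenience export: rows are sites, columns hosts, entries the filtered
#' frequencies (missing pairs become `NA`).
#'
#' @param freqs long frequency table (`site_id`, `host_id`, `f`).
#' @return numeric matrix with site ids as row names.
#' @export
frequency_wide <- function(freqs) {
  require_columns(freqs, c("site_id", "host_id", "f"), "frequency table")
  sites <- unique(freqs$site_id); hosts <- unique(freqs$host_id)
  m <- matrix(NA_real_, length(sites), length(hosts),
              dimnames = list(sites, hosts))
  m[cbind(match(freqs$site_id, sites), match(freqs$host_id, hosts))] <- freqs$f
  m
}
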