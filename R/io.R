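#' Read a growth-rate table
#'
#' Reads a delimited text file with header columns `strain_id`,
#' `temperature` (or `temperature_K`) and `rate`.  Temperatures given in
#' degrees Celsius are converted to Kelvin.  Malformed rows are reported
#' with their line numbers.
#'
#' @param path file path.
#' @param units `"K"` or `"C"` for the temperature column.
#' @param sep field separator.
#' @return data.frame with columns `strain_id`, `temperature_K`,
#'   `rate_obs` (plus any extra input columns), suitable for
#'   [standardize_rates()].
#' @export
read_growth_table <- function(path, units = c("K", "C"), sep = ",") {
  units <- match.arg(units)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty growth table: ", path)
  tcol <- intersect(c("temperature", "temperature_K", "temperature_C"),
                    names(df))[1]
  rcol <- intersect(c("rate", "rate_obs"), names(df))[1]
  if (!("strain_id" %in% names(df)) || is.na(tcol) || is.na(rcol))
    stop("growth table needs columns strain_id, temperature, rate")
  lines <- seq_len(nrow(df)) + 1L       # header is line 1
  Tv <- suppressWarnings(as.numeric(df[[tcol]]))
  rv <- suppressWarnings(as.numeric(df[[rcol]]))
  bad <- which(is.na(Tv) | is.na(rv))
  if (length(bad))
    stop("unparseable numbers at line(s) ", paste(lines[bad], collapse = ", "))
  if (units == "C" || identical(tcol, "temperature_C")) Tv <- Tv + 273.15
  neg <- which(rv < 0)
  if (length(neg))
    stop("negative rates at line(s) ", paste(lines[neg], collapse = ", "))
  dup <- which(duplicated(df[, c("strain_id", tcol)]))
  if (length(dup))
    stop("duplicate (strain, temperature) rows at line(s) ",
         paste(lines[dup], collapse = ", "))
  out <- df
  out[[tcol]] <- NULL; out[[rcol]] <- NULL
  out$temperature_K <- Tv
  out$rate_obs <- rv
  out
}

#' Write a growth-rate table
#'
#' Writes `strain_id,temperature_K,rate` CSV that round-trips through
#' [read_growth_table()].
#'
#' @param records data.frame with `strain_id`, `temperature_K`, `rate_obs`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_growth_table <- function(records, path) {
  utils::write.csv(
    data.frame(strain_id = records$strain_id,
               temperature_K = records$temperature_K,
               rate = records$rate_obs),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Posterior summary table in report form
#'
#' Universal and group-level posterior estimates formatted as
#' `"mean (lower, upper)"` with 99% HPDIs — the conventional presentation
#' of the headline parameter tables.
#'
#' @param fit a [thermo_fit] object.
#' @param digits significant digits.
#' @return data.frame with columns `parameter`, `mean`, `lower99`,
#'   `upper99`, `formatted`.
#' @export
posterior_summary_table <- function(fit, digits = 4) {
  p <- fit$posterior
  keep <- grepl("^u\\.|^mu\\.", p$parameter)
  out <- p[keep, c("parameter", "mean", "lower99", "upper99")]
  out$formatted <- mapply(format_hpdi, out$mean, out$lower99, out$upper99,
                          MoreArgs = list(digits = digits))
  rownames(out) <- NULL
  out
}

#' Write the derived-parameter group table
#'
#' @param tab output of [group_summary_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_group_summary <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records input/output paths with MD5 checksums, the seed, package version
#' and a timestamp, so a run can be verified and reproduced.
#'
#' @param path manifest JSON path.
#' @param files character vector of produced files.
#' @param seed integer seed used.
#' @param extra optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, files, seed, extra = list()) {
  manifest <- c(list(
    package = "thermogrowth",
    version = as.character(utils::packageVersion("thermogrowth")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
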