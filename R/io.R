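#' Delimited-text input/output helpers
#'
#' All artefacts are exchanged as plain tab-separated text with a header
#' line, so results can be inspected and diffed without R.
#'
#' @param x object to write
#' @param path file path
#' @name thalamr-io
NULL

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
}

#' @rdname thalamr-io
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "trace_record"), !is.null(x$trace))
  write_tsv_plain(x$trace, path)
}

#' @rdname thalamr-io
#' @export
read_trace <- function(path) read_tsv_plain(path)

#' @rdname thalamr-io
#' @export
write_raster <- function(x, path) {
  stopifnot(inherits(x, "raster_record"))
  write_tsv_plain(x$spikes, path)
}

#' @rdname thalamr-io
#' @export
read_raster <- function(path) read_tsv_plain(path)

#' @rdname thalamr-io
#' @export
write_rate_table <- function(x, path) write_tsv_plain(x, path)

#' @rdname thalamr-io
#' @export
read_rate_table <- function(path) read_tsv_plain(path)

#' @rdname thalamr-io
#' @export
write_trajectory <- function(x, path) write_tsv_plain(as_tibble(x), path)

#' @rdname thalamr-io
#' @export
read_trajectory <- function(path) {
  out <- read_tsv_plain(path)
  class(out) <- c("mf_trajectory", class(out))
  out
}

#' Write fitted transfer-function coefficients
#'
#' Stores the ten polynomial coefficients and the normalisation constants as
#' key-value text.
#'
#' @param x a `tf_coefficients` or `tf_fit`
#' @param path file path
#' @export
write_tf_coefficients <- function(x, path) {
  if (inherits(x, "tf_fit")) x <- x$coefficients
  stopifnot(inherits(x, "tf_coefficients"))
  df <- tibble(key = c(paste0("P", 0:9), names(x$norm)),
               value = c(unname(x$P), unname(unlist(x$norm))))
  write_tsv_plain(df, path)
}

#' @rdname write_tf_coefficients
#' @export
read_tf_coefficients <- function(path) {
  df <- read_tsv_plain(path)
  kv <- stats::setNames(df$value, df$key)
  norm <- as.list(kv[!grepl("^P[0-9]$", names(kv))])
  tf_coefficients(unname(kv[paste0("P", 0:9)]), norm = norm)
}

#' Regenerate the packaged example fixtures
#'
#' Writes small text fixtures (a sampled single-cell rate table and the
#' reference transfer-function coefficients) used by the examples and tests.
#'
#' @param dir output directory
#' @param seed integer seed
#' @return invisibly, the paths written
#' @export
make_fixtures <- function(dir = "inst/extdata", seed = 42L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "tf_coefficients_tc.tsv")
  write_tf_coefficients(tf_preset("TC"), p); paths <- c(paths, p)
  p <- file.path(dir, "tf_coefficients_re.tsv")
  write_tf_coefficients(tf_preset("RE"), p); paths <- c(paths, p)
  pars <- thalamic_cell_params("TC", "awake")
  ic <- input_connectivity(pars, K_e = 400, K_i = 25)
  grid <- tf_fit_grid(n_e = 8, nu_i_values = c(0, 10, 40))
  rt <- sample_single_cell_rates(pars, ic, grid, duration = 2000, reps = 2,
                                 seed = seed)
  p <- file.path(dir, "rate_table_tc_small.tsv")
  write_rate_table(rt, p); paths <- c(paths, p)
  invisible(paths)
}
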