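# Internal helpers shared across modules.

geomean <- function(x) exp(mean(log(x)))

mirnorm_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "mirnorm_error"))
}
stop_format <- function(msg) mirnorm_abort(msg, "mirnorm_format_error")
stop_data <- function(msg) mirnorm_abort(msg, "mirnorm_data_error")
stop_input <- function(msg) mirnorm_abort(msg, "mirnorm_input_error")
stop_config <- function(msg) mirnorm_abort(msg, "mirnorm_config_error")
stop_consistency <- function(msg) mirnorm_abort(msg, "mirnorm_consistency_error")

# Delimiter from file extension unless overridden.
sniff_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

read_delim_chr <- function(path, delim = NULL) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  readr::read_delim(
    path,
    delim = sniff_delim(path, delim),
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = FALSE, progress = FALSE,
    show_col_types = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
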