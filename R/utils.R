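`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || !all(is.finite(x)))
    stop_config("%s must be a finite numeric pair", name)
  if (x[1] <= 0) stop_config("%s must have a positive lower bound", name)
  if (x[1] > x[2]) stop_config("%s must satisfy lower <= upper", name)
  invisible(x)
}

check_fraction <- function(x, name, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (if (open_upper) x >= 1 else x > 1))
    stop_config("%s must be a probability in [0,%s", name,
                if (open_upper) "1)" else "1]")
  invisible(x)
}

# log-uniform draw over [lo, hi]; lo == hi returns the constant
runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
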