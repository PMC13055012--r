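#' Multi-echo BOLD series container
#'
#' Holds E co-registered 4D echo volumes acquired in the same run: one
#' `X x Y x Z x T` array per echo, a strictly ascending vector of echo times
#' in milliseconds, and the repetition time in seconds. All downstream stages
#' (decay fitting, echo combination, ICA denoising) consume this container.
#'
#' @param data List of E numeric 4D arrays with identical dimensions.
#' @param echo_times Numeric vector of echo times in milliseconds, strictly
#'   increasing and positive, one per echo.
#' @param tr Repetition time in seconds.
#'
#' @return An object of class `multi_echo_series` with elements `data`,
#'   `echo_times`, `tr`, `dims` (spatial grid) and `n_volumes`.
#' @export
multi_echo_series <- function(data, echo_times, tr) {
  stopifnot(is.list(data), length(data) >= 1L)
  dims <- dim(data[[1]])
  stopifnot(length(dims) == 4L)
  for (a in data) {
    if (!identical(dim(a), dims)) stop("all echo volumes must share one grid and length")
  }
  if (length(echo_times) != length(data))
    stop("need one echo time per echo volume")
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    stop("echo times must be positive and strictly increasing")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be a positive number of seconds")
  structure(
    list(data = data, echo_times = as.numeric(echo_times), tr = as.numeric(tr),
         dims = dims[1:3], n_volumes = dims[4]),
    class = "multi_echo_series"
  )
}

#' @export
print.multi_echo_series <- function(x, ...) {
  cat(sprintf("<multi_echo_series> %d echoes (TE %s ms), grid %s, %d volumes, TR %.3g s\n",
              length(x$data), paste(x$echo_times, collapse = "/"),
              paste(x$dims, collapse = "x"), x$n_volumes, x$tr))
  invisible(x)
}

n_echoes <- function(me) length(me$data)

# temporal mean image per echo: V x E matrix over the full grid
echo_means <- function(me) {
  nv <- prod(me$dims)
  m <- vapply(me$data, function(a) rowMeans(matrix(a, nrow = nv)), numeric(nv))
  matrix(m, nrow = nv)
}
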