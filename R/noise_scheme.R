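#' Ordinal noise classification schemes
#'
#' A noise scheme is an ordered set of contiguous dB(A) bands, ascending by
#' loudness; grid cells and exposure shares are expressed as indices into it.
#' Two schemes used for strategic road-traffic noise mapping ship as
#' built-ins:
#' \itemize{
#'   \item \code{"london6"}: six classes, <55.0, 55.0-59.9, 60.0-64.9,
#'     65.0-69.9, 70.0-74.9, >75.0 dB. The printed lower label of the
#'     quietest band (<54.9) is treated as contiguous at 55.0 since dB is
#'     continuous.
#'   \item \code{"brisbane5"}: five classes, <58, 58-63, 63-68, 68-73,
#'     >73 dB.
#' }
#'
#' @param name built-in name, or a label for a custom scheme
#' @param labels,lower,upper custom class labels and dB bounds (ascending by
#'   loudness; bounds must be contiguous and non-overlapping). Ignored for
#'   built-ins.
#' @return an object of class \code{noise_scheme} with fields \code{name},
#'   \code{labels}, \code{lower}, \code{upper}
#' @examples
#' sc <- noise_scheme("london6")
#' n_classes(sc)
#' @export
noise_scheme <- function(name = "london6", labels = NULL, lower = NULL, upper = NULL) {
  if (is.null(labels)) {
    if (identical(name, "london6")) {
      labels <- c("<55.0dB", "55.0-59.9dB", "60.0-64.9dB", "65.0-69.9dB",
                  "70.0-74.9dB", ">75.0dB")
      lower <- c(-Inf, 55, 60, 65, 70, 75)
      upper <- c(55, 60, 65, 70, 75, Inf)
    } else if (identical(name, "brisbane5")) {
      labels <- c("<58dB", "58-63dB", "63-68dB", "68-73dB", ">73dB")
      lower <- c(-Inf, 58, 63, 68, 73)
      upper <- c(58, 63, 68, 73, Inf)
    } else {
      rx_stop("invalid_config", sprintf("unknown noise scheme '%s'", name))
    }
  }
  k <- length(labels)
  if (k < 2L || k > 10L)
    rx_stop("invalid_config", "a noise scheme needs between 2 and 10 classes")
  if (length(lower) != k || length(upper) != k)
    rx_stop("invalid_config", "labels, lower and upper must have equal length")
  if (any(upper <= lower))
    rx_stop("invalid_config", "each class needs upper > lower")
  if (k > 1L && any(abs(lower[-1] - upper[-k]) > 1e-9))
    rx_stop("invalid_config", "classes must be contiguous on the dB axis")
  structure(list(name = name, labels = labels, lower = lower, upper = upper),
            class = "noise_scheme")
}

#' @rdname noise_scheme
#' @param scheme a \code{noise_scheme}
#' @export
n_classes <- function(scheme) length(scheme$labels)

#' @export
print.noise_scheme <- function(x, ...) {
  cat(sprintf("noise scheme '%s' (%d classes, quiet to loud):\n", x$name, n_classes(x)))
  cat(" ", paste(x$labels, collapse = " | "), "\n")
  invisible(x)
}

# Column-name slug for a class label, e.g. "<55.0dB" -> "lt55_0db".
label_slug <- function(label) {
  s <- tolower(label)
  s <- gsub("<", "lt", s, fixed = TRUE)
  s <- gsub(">", "gt", s, fixed = TRUE)
  s <- gsub("[^a-z0-9]+", "_", s)
  gsub("^_|_$", "", s)
}

noise_share_cols <- function(scheme) paste0("noise_share_", vapply(scheme$labels, label_slug, ""))

#' Read or write a noise scheme as JSON
#' @param scheme a \code{noise_scheme}
#' @param path file path
#' @return \code{read_noise_scheme} returns a \code{noise_scheme}
#' @export
write_noise_scheme <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_noise_scheme
#' @export
read_noise_scheme <- function(path) {
  x <- jsonlite::fromJSON(path)
  lo <- as.numeric(x$lower); up <- as.numeric(x$upper)
  lo[is.na(lo)] <- -Inf; up[is.na(up)] <- Inf   # JSON has no Inf
  noise_scheme(x$name, labels = as.character(x$labels), lower = lo, upper = up)
}
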