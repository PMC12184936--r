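#' @keywords internal
"_PACKAGE"

# Condition helper: every package error carries a class usable with
# tryCatch()/expect_error(class=). `class` is the specific error class,
# e.g. "routexpose_invalid_config".
rx_stop <- function(class, msg, ...) {
  fields <- list(...)
  cond <- errorCondition(msg, class = c(paste0("routexpose_", class), "routexpose_error"))
  if (length(fields)) cond[names(fields)] <- fields
  stop(cond)
}

rx_warn <- function(msg) warning(warningCondition(msg, class = "routexpose_warning"))

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. Every randomised operation in the package goes through this, so
# identical (input, seed) pairs give identical output regardless of what the
# session did before.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic per-stage seed derivation from one global seed; stays well
# below .Machine$integer.max.
derive_seed <- function(seed, k) {
  ((as.integer(seed) %% 1000003L) * 1009L + as.integer(k)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    rx_stop("invalid_config", sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_bbox <- function(bbox) {
  if (!is.numeric(bbox) || length(bbox) != 4L || anyNA(bbox))
    rx_stop("invalid_config", "bbox must be numeric c(xmin, ymin, xmax, ymax)")
  if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2])
    rx_stop("invalid_config", "bbox must have positive width and height")
  as.numeric(bbox)
}
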