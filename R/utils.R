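# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop_fw <- function(...) stop(sprintf(...), call. = FALSE)

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# axis-aligned rectangle in normalized cage/image coordinates
as_rect <- function(r) {
  stopifnot(is.list(r), all(c("xmin", "xmax", "ymin", "ymax") %in% names(r)))
  if (r$xmin >= r$xmax || r$ymin >= r$ymax) stop_fw("degenerate region: %s", deparse(r))
  r
}

in_rect <- function(x, y, rect) {
  x >= rect$xmin & x <= rect$xmax & y >= rect$ymin & y <= rect$ymax
}

# fold a free-running coordinate into [lo, hi] by reflection (triangle map)
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  ifelse(y > span, 2 * span - y, y) + lo
}

# FNV-1a 32-bit checksum of a string, in split 16-bit arithmetic so the
# products stay exactly representable in doubles
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)

# strictly increasing, uniformly spaced timestamps; returns the common step
check_uniform_times <- function(time_s, what = "series") {
  if (length(time_s) < 2) return(NA_real_)
  d <- diff(time_s)
  if (any(d <= 0)) stop_fw("%s timestamps must be strictly increasing", what)
  if (max(d) - min(d) > 1e-6 * max(d)) {
    stop_fw("%s timestamps are not uniformly spaced", what)
  }
  stats::median(d)
}
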