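#' Progressive type-II censoring scheme
#'
#' A progressive type-II censoring experiment places `n` units on test and
#' observes `m` failures.  Immediately after the i-th observed failure,
#' `removals[i]` of the surviving units are withdrawn from the test, so the
#' design must satisfy `sum(removals) + m == n`.  `removals` is 1-based and
#' has length `m`; all entries are nonnegative integers.
#'
#' With all removals zero (and `m == n`) the design reduces to a complete
#' sample of ordinary order statistics; with all withdrawals at the last
#' failure it is conventional type-II right censoring.
#'
#' @param n number of units on test.
#' @param m number of observed failures, `m <= n`.
#' @param removals integer vector `R_1..R_m` of withdrawals at each failure.
#' @return A validated object of class `"censoring_scheme"`.
#' @examples
#' censoring_scheme(23, 18, c(rep(0, 11), 1, 0, 1, 0, 1, 0, 2))
#' build_scheme("I", 25, 15)  # all withdrawals at the first failure
#' @export
censoring_scheme <- function(n, m, removals) {
  stopifnot(is.numeric(n), length(n) == 1L, is.numeric(m), length(m) == 1L)
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1L) stop("'m' must be at least 1")
  if (m > n) stop("'m' must not exceed 'n' (m = ", m, ", n = ", n, ")")
  removals <- as.integer(removals)
  if (length(removals) != m)
    stop("'removals' must have length m = ", m,
         ", got ", length(removals))
  if (any(removals < 0))
    stop("negative removal count at position ",
         which(removals < 0)[1])
  if (sum(removals) + m != n)
    stop("scheme constraint violated: sum(removals) + m = ",
         sum(removals) + m, " but n = ", n)
  structure(list(n = n, m = m, removals = removals),
            class = "censoring_scheme")
}

#' @rdname censoring_scheme
#' @param scheme an object to validate.
#' @export
validate_scheme <- function(scheme) {
  if (!inherits(scheme, "censoring_scheme"))
    stop("'scheme' must be a 'censoring_scheme' object")
  censoring_scheme(scheme$n, scheme$m, scheme$removals)
}

#' @export
print.censoring_scheme <- function(x, ...) {
  cat(sprintf("Progressive type-II censoring scheme: n = %d, m = %d\n",
              x$n, x$m))
  cat("R =", paste(x$removals, collapse = " "), "\n")
  invisible(x)
}

#' Canonical one-point removal schemes
#'
#' The three designs used throughout the simulation study: scheme I removes
#' all `n - m` surplus units at the first observed failure, scheme II at the
#' middle failure (position `(m+1)/2` for odd `m`, `m/2` for even `m`), and
#' scheme III at the last failure (equivalent to type-II right censoring).
#'
#' @param kind `"I"`, `"II"` or `"III"` (also accepts `1:3`).
#' @param n,m design sizes, `1 <= m <= n`.
#' @return A [censoring_scheme()].
#' @export
build_scheme <- function(kind, n, m) {
  kind <- as.character(kind)
  kind <- c("1" = "I", "2" = "II", "3" = "III")[kind] %||% kind
  if (!kind %in% c("I", "II", "III"))
    stop("unknown scheme kind '", kind, "' (expected I, II or III)")
  n <- as.integer(n); m <- as.integer(m)
  stopifnot(m >= 1L, m <= n)
  R <- integer(m)
  pos <- switch(kind,
                I = 1L,
                II = if (m %% 2L == 1L) (m + 1L) %/% 2L else m %/% 2L,
                III = m)
  R[pos] <- n - m
  censoring_scheme(n, m, R)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || is.na(a)) b else a
}

#' Progressively censored sample container
#'
#' Couples a [censoring_scheme()] with the `m` observed ordered failure
#' times.  Times must be strictly increasing and positive.
#'
#' @param scheme a [censoring_scheme()].
#' @param times numeric vector of length `scheme$m`, strictly increasing,
#'   all positive.
#' @return An object of class `"prog_cens_sample"`.
#' @export
prog_cens_sample <- function(scheme, times) {
  scheme <- validate_scheme(scheme)
  times <- as.numeric(times)
  if (length(times) != scheme$m)
    stop("'times' must have length m = ", scheme$m)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("failure times must be positive and finite")
  if (any(diff(times) <= 0))
    stop("failure times must be strictly increasing")
  structure(list(scheme = scheme, times = times),
            class = "prog_cens_sample")
}

#' @export
print.prog_cens_sample <- function(x, ...) {
  print(x$scheme)
  cat("times:", paste(signif(x$times, 6), collapse = " "), "\n")
  invisible(x)
}

#' Simulate a progressive type-II censored sample
#'
#' Draws one sample from the exact joint law of progressively censored order
#' statistics under `scheme`, for lifetimes following `params`.  Uses the
#' uniform-spacings transformation: independent uniforms are raised to the
#' reciprocal of the cumulative number of units still at risk counting from
#' the largest observation, their cumulative products give the joint law of
#' uniform progressive order statistics, and the quantile function maps them
#' to lifetimes.  Floating-point ties (probability zero) trigger a
#' regeneration.
#'
#' Deterministic under `set.seed()`.
#'
#' @param scheme a [censoring_scheme()].
#' @param params a [phfd()] object.
#' @return A [prog_cens_sample()].
#' @examples
#' set.seed(1)
#' rprogressive(build_scheme("I", 10, 5), phfd(1.092, 0.332))
#' @export
rprogressive <- function(scheme, params) {
  scheme <- validate_scheme(scheme)
  params <- as_phfd(params)
  for (attempt in 1:100) {
    u <- runif_prog_uniform(scheme)
    x <- qphfd(u, params)
    if (all(diff(x) > 0)) return(prog_cens_sample(scheme, x))
  }
  stop("could not generate a tie-free sample in 100 attempts")
}

# joint draw of uniform progressive type-II order statistics
# (Balakrishnan-Sandhu transformation)
runif_prog_uniform <- function(scheme) {
  m <- scheme$m; R <- scheme$removals
  w <- stats::runif(m)
  # gamma_i = i + R_m + R_{m-1} + ... + R_{m-i+1}
  gam <- seq_len(m) + cumsum(rev(R))
  v <- w^(1 / gam)
  # u_i = 1 - v_m * v_{m-1} * ... * v_{m-i+1}
  1 - cumprod(rev(v))
}

#' Simulate the censoring process literally
#'
#' Cross-validation oracle for [rprogressive()]: simulates all `n`
#' individual lifetimes, then walks the experiment forward, recording the
#' smallest remaining lifetime at each step and deleting `R_i` randomly
#' chosen survivors after the i-th observed failure.  Slower but follows the
#' physical withdrawal process exactly as described.
#'
#' @inheritParams rprogressive
#' @return A [prog_cens_sample()].
#' @export
rprogressive_naive <- function(scheme, params) {
  scheme <- validate_scheme(scheme)
  params <- as_phfd(params)
  pool <- rphfd(scheme$n, params)
  times <- numeric(scheme$m)
  for (i in seq_len(scheme$m)) {
    k <- which.min(pool)
    times[i] <- pool[k]
    pool <- pool[-k]
    r <- scheme$removals[i]
    if (r > 0) {
      drop <- sample.int(length(pool), r)
      pool <- pool[-drop]
    }
  }
  prog_cens_sample(scheme, times)
}

#' Read and write censored-sample files
#'
#' The file format is deliberately trivial: UTF-8 delimited text with
#' `#`-prefixed comment lines, a required comment header
#' `# n=<int> m=<int>` (optionally `beta=<real>`), a `time,removed` header
#' line, and one `time,removed` row per observed failure in ascending time
#' order.  `read_cens_sample` validates monotonicity and the scheme-sum
#' constraint against the declared `n`.
#'
#' @param path file path.
#' @return `read_cens_sample`: a [prog_cens_sample()], with the declared
#'   `beta` (if any) attached as attribute `"beta"`.
#' @examples
#' f <- system.file("extdata", "ballbearing_progcens.csv",
#'                  package = "phfdlpi")
#' read_cens_sample(f)
#' @export
read_cens_sample <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  comments <- lines[startsWith(trimws(lines), "#")]
  hdr <- paste(comments, collapse = " ")
  get_field <- function(key) {
    mt <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([0-9.eE+-]+)"), hdr))[[1]]
    if (length(mt) < 2) NA_real_ else as.numeric(mt[2])
  }
  n <- get_field("n"); m_decl <- get_field("m"); beta <- get_field("beta")
  if (is.na(n) || is.na(m_decl))
    stop("missing required comment header '# n=<int> m=<int>' in ", path)
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(body) < 1L || trimws(body[1]) != "time,removed")
    stop("expected header line 'time,removed' in ", path)
  rows <- strsplit(body[-1], ",")
  if (any(lengths(rows) != 2L))
    stop("malformed row in ", path, " (expected 'time,removed')")
  times <- as.numeric(vapply(rows, `[[`, "", 1L))
  removed <- as.numeric(vapply(rows, `[[`, "", 2L))
  if (any(is.na(times)) || any(is.na(removed)))
    stop("non-numeric entry in ", path)
  if (length(times) != m_decl)
    stop("declared m = ", m_decl, " but file has ", length(times), " rows")
  if (any(diff(times) <= 0))
    stop("failure times out of order in ", path)
  scheme <- censoring_scheme(n, m_decl, removed)  # checks sum(R) + m == n
  out <- prog_cens_sample(scheme, times)
  attr(out, "beta") <- if (is.na(beta)) NULL else beta
  out
}

#' @rdname read_cens_sample
#' @param sample a [prog_cens_sample()].
#' @param beta optional known shape parameter recorded in the header.
#' @export
write_cens_sample <- function(sample, path, beta = NULL) {
  stopifnot(inherits(sample, "prog_cens_sample"))
  hdr <- sprintf("# n=%d m=%d%s", sample$scheme$n, sample$scheme$m,
                 if (is.null(beta)) "" else sprintf(" beta=%.10g", beta))
  rows <- sprintf("%.10g,%d", sample$times, sample$scheme$removals)
  writeLines(c(hdr, "time,removed", rows), path)
  invisible(path)
}

#' The progressively censored ball-bearing fatigue data
#'
#' Convenience loader for the bundled fixture: 18 observed failures (in
#' millions of revolutions, scaled) out of 23 deep-groove ball bearings on
#' test, with removal counts applied at the 12th, 14th, 16th and 18th
#' observed failures.  The shape parameter for this dataset is taken as
#' known, `beta = 0.332`.
#'
#' @return A [prog_cens_sample()] with attribute `"beta"`.
#' @export
ballbearing_sample <- function() {
  read_cens_sample(system.file("extdata", "ballbearing_progcens.csv",
                               package = "phfdlpi", mustWork = TRUE))
}
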