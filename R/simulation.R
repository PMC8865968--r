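#' Monte-Carlo study configuration
#'
#' Describes a coverage / mean-squared-error study for the lifetime
#' performance index estimators over a grid of progressive censoring
#' designs.  The default arguments reproduce the canonical evaluation
#' design: true PHFD(1.092, 0.332), lower specification limit 0.022, 1000
#' replicates per cell, level 95%, and two informative gamma priors
#' (a, b) = (1, 2) and (2, 3).
#'
#' @param true_params the data-generating [phfd()] parameters.
#' @param l_x lower specification limit used by every estimator.
#' @param cells data.frame with columns `n`, `m`, `scheme` (scheme kind
#'   `"I"`, `"II"` or `"III"`); each row is one study cell.
#' @param priors list of [gamma_prior()] objects (may be empty).
#' @param reps replicates per cell, `>= 1`.
#' @param delta significance level of the one-sided bounds.
#' @param master_seed integer seed; per-replicate sub-streams are derived
#'   from it by a fixed linear-congruential hash of
#'   `(master_seed, cell index, replicate index)`, so cells are
#'   reproducible independently of execution order.
#' @return A validated list of class `"mc_config"`.
#' @export
mc_config <- function(true_params = phfd(1.092, 0.332),
                      l_x = 0.022,
                      cells = data.frame(
                        n = rep(c(25, 30, 30, 50, 50, 70, 90, 90), each = 3),
                        m = rep(c(15, 20, 25, 30, 40, 50, 60, 70), each = 3),
                        scheme = rep(c("I", "II", "III"), times = 8)),
                      priors = list(gamma_prior(1, 2), gamma_prior(2, 3)),
                      reps = 1000,
                      delta = 0.05,
                      master_seed = 1L) {
  true_params <- as_phfd(true_params)
  stopifnot(is.data.frame(cells), all(c("n", "m", "scheme") %in% names(cells)),
            reps >= 1, delta > 0, delta < 1, l_x >= 0)
  for (i in seq_len(nrow(cells)))   # every cell must be constructible
    build_scheme(cells$scheme[i], cells$n[i], cells$m[i])
  stopifnot(all(vapply(priors, inherits, TRUE, "gamma_prior")))
  structure(list(true_params = true_params, l_x = l_x, cells = cells,
                 priors = priors, reps = as.integer(reps), delta = delta,
                 master_seed = as.integer(master_seed)),
            class = "mc_config")
}

# deterministic sub-stream seed for (master, cell, replicate): two chained
# Lehmer steps so that neighbouring replicate indices map to well-separated
# seeds; all arithmetic in doubles, exact below 2^53, result in [1, 2^31-1]
derive_seed <- function(master, cell_idx, rep_idx) {
  M <- 2147483647
  s <- as.numeric(master) %% M
  s <- (s * 48271 + cell_idx) %% M
  s <- (s * 48271 + rep_idx) %% M
  as.integer(s + 1)
}

#' Run one study cell
#'
#' Simulates `reps` progressively censored samples under one design,
#' computes the ML and Bayes index estimates and their one-sided lower
#' bounds for each replicate, and summarises mean squared error against the
#' true index and empirical coverage (fraction of replicates whose lower
#' bound does not exceed the true index).  Bounds use the exact-pivot
#' (`calibrated = TRUE`) convention of [lower_bound_ml()], under which the
#' ML coverage is exactly `1 - delta` for every design.
#'
#' @param n,m,scheme_kind the cell design.
#' @param config an [mc_config()].
#' @param cell_idx index used for sub-stream seed derivation (set
#'   automatically by [run_study()]).
#' @return A one-row data.frame: `n`, `m`, `scheme`, `c_true`, `reps`,
#'   `mse_ml`, `cp_ml`, then `mse_bayes<i>` / `cp_bayes<i>` per prior.
#' @export
run_cell <- function(n, m, scheme_kind, config, cell_idx = 1L) {
  stopifnot(inherits(config, "mc_config"))
  scheme <- build_scheme(scheme_kind, n, m)
  tp <- config$true_params
  c_true <- c_index(tp, config$l_x)
  npr <- length(config$priors)
  chat_ml <- lb_ml <- numeric(config$reps)
  chat_bs <- lb_bs <- matrix(0, config$reps, max(npr, 1))
  for (r in seq_len(config$reps)) {
    set.seed(derive_seed(config$master_seed, cell_idx, r))
    smp <- rprogressive(scheme, tp)
    chat_ml[r] <- mle_c(smp, tp$beta, config$l_x)
    lb_ml[r] <- lower_bound_ml(chat_ml[r], m, tp$beta, config$delta,
                               calibrated = TRUE)
    for (j in seq_len(npr)) {
      pr <- config$priors[[j]]
      chat_bs[r, j] <- bayes_c(smp, tp$beta, config$l_x, pr)
      lb_bs[r, j] <- lower_bound_bayes(chat_bs[r, j], m, pr$a, tp$beta,
                                       config$delta, calibrated = TRUE)
    }
  }
  out <- data.frame(n = n, m = m, scheme = scheme_kind, c_true = c_true,
                    reps = config$reps,
                    mse_ml = mean((chat_ml - c_true)^2),
                    cp_ml = mean(lb_ml <= c_true))
  for (j in seq_len(npr)) {
    out[[paste0("mse_bayes", j)]] <- mean((chat_bs[, j] - c_true)^2)
    out[[paste0("cp_bayes", j)]] <- mean(lb_bs[, j] <= c_true)
  }
  out
}

#' Run the full Monte-Carlo study
#'
#' Executes [run_cell()] for every row of `config$cells`.  Bit-identical
#' under a fixed `master_seed` regardless of cell order.
#'
#' @param config an [mc_config()].
#' @return An object of class `"mc_result"`: the per-cell data.frame with
#'   the configuration attached as attribute `"config"`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  rows <- lapply(seq_len(nrow(config$cells)), function(i) {
    run_cell(config$cells$n[i], config$cells$m[i], config$cells$scheme[i],
             config, cell_idx = i)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("mc_result", class(out))
  out
}

#' Format a study result
#'
#' Renders the per-cell records with MSEs to 6 decimals and coverage
#' probabilities to 3, in the conventional column order (ML first, then one
#' Bayes block per prior; MSE block before CP block).
#'
#' @param result an `"mc_result"` (or compatible data.frame).
#' @param format `"text"` for an aligned table, `"csv"` for delimited.
#' @return A character vector of lines (invisibly printed-ready).
#' @export
summarize_study <- function(result, format = c("text", "csv")) {
  format <- match.arg(format)
  npr <- sum(grepl("^mse_bayes", names(result)))
  mse_cols <- c("mse_ml", if (npr) paste0("mse_bayes", seq_len(npr)))
  cp_cols <- c("cp_ml", if (npr) paste0("cp_bayes", seq_len(npr)))
  hdr <- c("n", "m", "scheme", mse_cols, cp_cols)
  if (nrow(result) == 0L) {
    return(if (format == "csv") paste(hdr, collapse = ",")
           else paste(formatC(hdr, width = 12), collapse = ""))
  }
  body <- data.frame(n = result$n, m = result$m, scheme = result$scheme)
  for (cc in mse_cols) body[[cc]] <- sprintf("%.6f", result[[cc]])
  for (cc in cp_cols) body[[cc]] <- sprintf("%.3f", result[[cc]])
  if (format == "csv") {
    c(paste(hdr, collapse = ","),
      apply(body, 1, paste, collapse = ","))
  } else {
    widths <- pmax(nchar(hdr), 10)
    fmt_row <- function(vals) paste(mapply(formatC, vals, width = widths),
                                    collapse = " ")
    c(fmt_row(hdr), apply(body, 1, fmt_row))
  }
}

#' Read a study configuration file
#'
#' Flat key-value text format, one `key: value` per line, `#` comments
#' allowed.  Keys: `true_alpha`, `true_beta`, `l_x`, `delta`, `reps`,
#' `seed`, `cells` (semicolon-separated `n,m,scheme` triples), `priors`
#' (semicolon-separated `a,b` pairs).  Missing keys fall back to the
#' [mc_config()] defaults.
#'
#' @param path file path.
#' @return An [mc_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed config line: ", ln)
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = ":"))
  }
  num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  args <- list(
    true_params = phfd(num("true_alpha", 1.092), num("true_beta", 0.332)),
    l_x = num("l_x", 0.022), delta = num("delta", 0.05),
    reps = num("reps", 1000), master_seed = num("seed", 1))
  if (!is.null(kv$cells)) {
    trip <- strsplit(strsplit(kv$cells, ";")[[1]], ",")
    args$cells <- data.frame(
      n = as.integer(vapply(trip, function(t) trimws(t[1]), "")),
      m = as.integer(vapply(trip, function(t) trimws(t[2]), "")),
      scheme = vapply(trip, function(t) trimws(t[3]), ""))
  }
  if (!is.null(kv$priors)) {
    pr <- strsplit(strsplit(kv$priors, ";")[[1]], ",")
    args$priors <- lapply(pr, function(p)
      gamma_prior(as.numeric(p[1]), as.numeric(p[2])))
  }
  do.call(mc_config, args)
}
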