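#' @name simulation_engine
#' @title Monte Carlo rejection-rate studies
#'
#' @description Drivers that estimate empirical type-I-error rates (null
#' scenarios) and power (correlated bivariate normal) for the four agreement
#' tests over a grid of scenarios and sample sizes. One dataset is drawn per
#' replicate and all requested tests are applied to it; the two permutation
#' tests share their shuffles. Rejection uses `p <= alpha`; permutation
#' p-values themselves use strict exceedance, so with `B = 1000` a p-value
#' of exactly 0.05 is attainable and counts as a rejection.
#'
#' Each (scenario, n) cell runs under its own seed derived deterministically
#' from the master seed and the cell labels, so cells are individually
#' reproducible and insensitive to grid order.
NULL

all_methods <- c("f_test", "fisher_z", "permute", "stu_permute")

# deterministic 31-bit hash of the master seed plus cell labels
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character,
                                              character(1L))),
               collapse = "|")
  h <- 17
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}

run_cell <- function(gen, n, n_reps, B, alpha, methods, cell_seed) {
  rej <- stats::setNames(numeric(length(methods)), methods)
  need_perm <- any(c("permute", "stu_permute") %in% methods)
  set.seed(cell_seed)
  for (rep in seq_len(n_reps)) {
    m <- gen(n)
    x <- m[, 1L]
    y <- m[, 2L]
    if ("f_test" %in% methods || "fisher_z" %in% methods) {
      ms <- mean_squares(ratings_matrix(m))
      if ("f_test" %in% methods) {
        f <- ms$msb / ((ms$ssr + ms$sse) / n)
        p <- stats::pf(f, n - 1, n, lower.tail = FALSE)
        rej[["f_test"]] <- rej[["f_test"]] + (p <= alpha)
      }
      if ("fisher_z" %in% methods) {
        denom <- ms$msb + ms$msw + (2 / n) * (ms$msr - ms$msw)
        rho <- (ms$msb - ms$msw) / denom
        # the estimate can fall below -1 in extreme samples; the one-sided
        # upper-tail p is then 1
        p <- if (rho <= -1) 1 else
          stats::pnorm(atanh(rho) * sqrt(n - 3), lower.tail = FALSE)
        rej[["fisher_z"]] <- rej[["fisher_z"]] + (p <= alpha)
      }
    }
    if (need_perm) {
      kern <- perm_kernel(x, y, B)
      if ("permute" %in% methods) {
        p <- perm_pvalue(kern$rho_obs, kern$rho_perm)
        rej[["permute"]] <- rej[["permute"]] + (p <= alpha)
      }
      if ("stu_permute" %in% methods) {
        p <- perm_pvalue(kern$rho_obs / sqrt(kern$tau2_obs),
                         kern$rho_perm / sqrt(kern$tau2_perm))
        rej[["stu_permute"]] <- rej[["stu_permute"]] + (p <= alpha)
      }
    }
  }
  rej / n_reps
}

sim_table_rows <- function(scenario, param, gen, sizes, n_reps, B, alpha,
                           methods, seed) {
  out <- list()
  for (n in sizes) {
    cell_seed <- derive_seed(seed, scenario,
                             if (is.null(param)) "" else param, n)
    rate <- run_cell(gen, n, n_reps, B, alpha, methods, cell_seed)
    out[[length(out) + 1L]] <- data.frame(
      scenario = scenario,
      param = if (is.null(param)) NA_real_ else param,
      n = as.integer(n),
      method = methods,
      rejections = as.integer(round(rate * n_reps)),
      n_reps = as.integer(n_reps),
      rate = as.numeric(rate),
      mc_se = sqrt(rate * (1 - rate) / n_reps),
      B = as.integer(B),
      alpha = alpha,
      seed = cell_seed,
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' Type-I-error study over null scenarios
#'
#' For each (scenario, n) cell, draws `n_reps` datasets, applies the
#' requested tests to each, and records the fraction of replicates with
#' `p <= alpha` together with its Monte Carlo standard error
#' `sqrt(rate * (1 - rate) / n_reps)`.
#'
#' @param scenarios Character vector of null scenario names, or a list whose
#'   elements are either names or `list(name =, param =)` pairs (needed for
#'   `mvnx`).
#' @param sizes Integer vector of subject counts.
#' @param n_reps Monte Carlo replicates per cell.
#' @param B Permutations per permutation test.
#' @param alpha Nominal level in (0, 1).
#' @param seed Master seed; per-cell seeds are derived from it by hashing
#'   the cell labels.
#' @param methods Subset of `c("f_test", "fisher_z", "permute",
#'   "stu_permute")` to run.
#' @return A data frame of class `"icc_sim_table"`, one row per
#'   (scenario, n, method), columns `scenario, param, n, method, rejections,
#'   n_reps, rate, mc_se, B, alpha, seed`.
#' @examples
#' type1_study("mvn", sizes = 10, n_reps = 50, B = 50, seed = 1)
#' @export
type1_study <- function(scenarios, sizes, n_reps = 10000L, B = 1000L,
                        alpha = 0.05, seed = 1L, methods = all_methods) {
  check_sim_args(sizes, n_reps, B, alpha, methods)
  if (is.character(scenarios)) scenarios <- as.list(scenarios)
  if (length(scenarios) == 0L) stop("empty scenario grid", call. = FALSE)
  rows <- lapply(scenarios, function(sc) {
    if (is.character(sc)) sc <- list(name = sc, param = NULL)
    name <- resolve_scenario(sc$name)
    param <- sc$param
    gen <- function(n) scenario_registry[[name]](n, param)
    sim_table_rows(name, param, gen, sizes, n_reps, B, alpha, methods, seed)
  })
  new_sim_table(do.call(rbind, rows), kind = "type1", master_seed = seed)
}

#' Power study under correlated bivariate normal data
#'
#' Same mechanics as [type1_study()] over [generate_power()] draws: the
#' rejection rate is the empirical power at true ICC equal to `rho`.
#'
#' @param rhos Numeric vector of correlations in (0, 1).
#' @inheritParams type1_study
#' @return An `"icc_sim_table"` data frame; `scenario` is `"bvn_rho"` and
#'   `param` holds `rho`.
#' @examples
#' power_study(0.6, sizes = 15, n_reps = 50, B = 50, seed = 1)
#' @export
power_study <- function(rhos, sizes, n_reps = 10000L, B = 1000L,
                        alpha = 0.05, seed = 1L, methods = all_methods) {
  check_sim_args(sizes, n_reps, B, alpha, methods)
  if (length(rhos) == 0L) stop("empty rho grid", call. = FALSE)
  if (any(!is.finite(rhos) | rhos <= 0 | rhos >= 1)) {
    stop("every 'rho' must lie in (0, 1)", call. = FALSE)
  }
  rows <- lapply(rhos, function(rho) {
    gen <- function(n) scenario_registry[["bvn_rho"]](n, rho)
    sim_table_rows("bvn_rho", rho, gen, sizes, n_reps, B, alpha, methods,
                   seed)
  })
  new_sim_table(do.call(rbind, rows), kind = "power", master_seed = seed)
}

check_sim_args <- function(sizes, n_reps, B, alpha, methods) {
  if (length(sizes) == 0L || any(sizes < 3 | sizes != round(sizes))) {
    stop("'sizes' must be integers >= 3", call. = FALSE)
  }
  if (n_reps < 1 || n_reps != round(n_reps)) {
    stop("'n_reps' must be a positive integer", call. = FALSE)
  }
  if (B < 1 || B != round(B)) stop("'B' must be a positive integer",
                                   call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  bad <- setdiff(methods, all_methods)
  if (length(methods) == 0L || length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(all_methods, collapse = ", "), call. = FALSE)
  }
}

new_sim_table <- function(df, kind, master_seed) {
  attr(df, "kind") <- kind
  attr(df, "master_seed") <- master_seed
  class(df) <- c("icc_sim_table", "data.frame")
  df
}

#' Summarize a simulation table
#'
#' @param table An `"icc_sim_table"` from [type1_study()] or
#'   [power_study()].
#' @return A list with `long` (the table itself, plain data frame) and
#'   `wide` (one row per scenario/param/n, one rejection-rate column per
#'   method plus matching `mc_se` columns), mirroring the usual
#'   scenario-by-size presentation of such studies.
#' @export
summarize_simulation <- function(table) {
  if (!inherits(table, "icc_sim_table") || nrow(table) == 0L) {
    stop("'table' must be a non-empty simulation table", call. = FALSE)
  }
  long <- as.data.frame(table)
  keys <- unique(long[c("scenario", "param", "n")])
  methods <- unique(long$method)
  wide <- keys
  key_of <- function(d) paste(d$scenario, d$param, d$n, sep = "\r")
  for (m in methods) {
    sub <- long[long$method == m, ]
    i <- match(key_of(keys), key_of(sub))
    wide[[m]] <- sub$rate[i]
    wide[[paste0(m, "_se")]] <- sub$mc_se[i]
  }
  rownames(wide) <- NULL
  list(long = long, wide = wide)
}

#' Write a simulation table to CSV files
#'
#' Writes `<prefix>_long.csv` (one row per scenario/n/method, all metadata
#' columns) and `<prefix>_wide.csv` (the per-scenario grid of
#' [summarize_simulation()]).
#'
#' @inheritParams summarize_simulation
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix, default the table kind
#'   (`"type1"`/`"power"`).
#' @return Invisibly, the two file paths.
#' @export
write_simulation <- function(table, dir, prefix = NULL) {
  if (is.null(prefix)) prefix <- attr(table, "kind")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- summarize_simulation(table)
  long_path <- file.path(dir, paste0(prefix, "_long.csv"))
  wide_path <- file.path(dir, paste0(prefix, "_wide.csv"))
  # doubles are written with 17 significant digits so a read-back reproduces
  # every rate bit-exactly
  fmt <- function(df) {
    for (nm in names(df)) {
      if (is.double(df[[nm]])) {
        df[[nm]] <- ifelse(is.na(df[[nm]]), NA, sprintf("%.17g", df[[nm]]))
      }
    }
    df
  }
  utils::write.csv(fmt(s$long), long_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(s$wide), wide_path, row.names = FALSE, quote = FALSE)
  invisible(c(long = long_path, wide = wide_path))
}
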