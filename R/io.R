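cycle_columns <- c("time_h", "voltage_v", "cod_mg_l", "no3n_mg_l",
                   "no2n_mg_l", "nh4n_mg_l")

#' Write a batch cycle to CSV
#'
#' The interchange dialect: reactor metadata as \code{# key=value}
#' comment lines, then a header row and the six data columns
#' (\code{time_h, voltage_v, cod_mg_l, no3n_mg_l, no2n_mg_l,
#' nh4n_mg_l}); unmeasured values are blank.
#'
#' @param cycle A \code{\link{batch_cycle}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cycle_csv <- function(cycle, path) {
  stopifnot(inherits(cycle, "batch_cycle"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(cycle$reactor))
    writeLines(sprintf("# %s=%.15g", nm, cycle$reactor[[nm]]), con)
  utils::write.csv(cycle$data, con, row.names = FALSE, na = "")
  invisible(path)
}

# parse '# key=value' comment lines into a named list
read_header_metadata <- function(path) {
  lines <- readLines(path, n = 50)
  meta <- list()
  for (ln in lines[grepl("^\\s*#", lines)]) {
    kv <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_0-9]+)\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- as.numeric(kv[3])
  }
  meta
}

#' Read batch cycles from a CSV file
#'
#' Reads the dialect written by \code{\link{write_cycle_csv}}.  Reactor
#' metadata comes from \code{# key=value} header comments, overridden by
#' the \code{reactor} argument if supplied.  Files holding several
#' concatenated cycles are split at the medium-replacement boundary: a
#' run of at least \code{debounce} consecutive samples below
#' \code{end_voltage_v} ends a cycle, and the next cycle starts (with
#' time rebased to zero) at the first sample after the run.
#'
#' @param path CSV file path.
#' @param reactor Optional \code{\link{reactor_config}} overriding file
#'   metadata.
#' @param end_voltage_v Cycle-boundary voltage threshold (V).
#' @param debounce Consecutive sub-threshold samples required to call a
#'   boundary.
#' @return List of \code{\link{batch_cycle}} objects.
#' @export
read_cycle_csv <- function(path, reactor = NULL, end_voltage_v = 0.02,
                           debounce = 3) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_header_metadata(path)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("time_h", "voltage_v", "cod_mg_l", "no3n_mg_l"),
                          names(df))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "))
  for (nm in setdiff(cycle_columns, names(df))) df[[nm]] <- NA_real_
  bad <- which(diff(df$time_h) <= 0)
  # time may legitimately rebase to zero at a cycle boundary
  bad <- setdiff(bad, split_points(df$voltage_v, end_voltage_v, debounce))
  if (length(bad))
    stop("non-monotone time at row ", bad[1] + 1, " of ", path)
  if (is.null(reactor)) {
    known <- intersect(names(meta), names(formals(reactor_config)))
    reactor <- do.call(reactor_config, meta[known])
  }
  groups <- split_cycle_groups(df, end_voltage_v, debounce)
  lapply(groups, function(g) {
    if (any(diff(g$time_h) <= 0))
      stop("non-monotone time within a cycle in ", path)
    batch_cycle(time_h = g$time_h - g$time_h[1],
                voltage_v = g$voltage_v, cod_mg_l = g$cod_mg_l,
                no3n_mg_l = g$no3n_mg_l, no2n_mg_l = g$no2n_mg_l,
                nh4n_mg_l = g$nh4n_mg_l, reactor = reactor)
  })
}

# indices at which a debounced sub-threshold run ends
split_points <- function(voltage, thr, debounce) {
  below <- voltage < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  ends[r$values & r$lengths >= debounce]
}

# split a multi-cycle data frame at debounced sub-threshold voltage runs
split_cycle_groups <- function(df, thr, debounce) {
  cuts <- split_points(df$voltage_v, thr, debounce)
  cuts <- cuts[cuts < nrow(df)]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nrow(df))
  groups <- Map(function(a, b) df[a:b, , drop = FALSE], starts, ends)
  groups[vapply(groups, nrow, integer(1)) >= 2]
}

#' Write a polarization curve or voltammogram to CSV
#'
#' @param x A \code{polarization_curve} (columns \code{resistance_ohm,
#'   voltage_v}) or \code{voltammogram} (columns \code{potential_v,
#'   current_a, segment}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_electrochem_csv <- function(x, path) {
  if (inherits(x, "polarization_curve")) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("# cathode_area_m2=%.15g", x$cathode_area_m2), con)
    utils::write.csv(x$points[, c("resistance_ohm", "voltage_v")], con,
                     row.names = FALSE)
  } else if (inherits(x, "voltammogram")) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("# scan_rate_v_s=%.15g", x$scan_rate_v_s), con)
    utils::write.csv(x$data, con, row.names = FALSE)
  } else stop("x must be a polarization_curve or voltammogram")
  invisible(path)
}

#' Read a polarization CSV (resistance_ohm, voltage_v)
#' @param path CSV path.
#' @param cathode_area_m2 Cathode area; overrides file metadata.
#' @return A \code{\link{polarization_curve}}.
#' @export
read_polarization_csv <- function(path, cathode_area_m2 = NULL) {
  meta <- read_header_metadata(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("resistance_ohm", "voltage_v") %in% names(df)))
    stop("schema error in ", path,
         ": need columns resistance_ohm, voltage_v")
  area <- cathode_area_m2 %||% meta$cathode_area_m2 %||% 7e-4
  polarization_curve(df$resistance_ohm, df$voltage_v,
                     cathode_area_m2 = area)
}

#' Read a voltammogram CSV (potential_v, current_a[, segment])
#' @param path CSV path.
#' @param scan_rate_v_s Scan rate; overrides file metadata.
#' @return A \code{\link{voltammogram}}.
#' @export
read_cv_csv <- function(path, scan_rate_v_s = NULL) {
  meta <- read_header_metadata(path)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!all(c("potential_v", "current_a") %in% names(df)))
    stop("schema error in ", path, ": need columns potential_v, current_a")
  voltammogram(df$potential_v, df$current_a,
               scan_rate_v_s = scan_rate_v_s %||% meta$scan_rate_v_s %||% 0.001,
               segment = if ("segment" %in% names(df)) df$segment else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full electron-flux pipeline over a set of cycle files
#'
#' For every batch cycle found in \code{paths}: electron balance
#' (CE/CCE, fractions), first-order nitrate kinetics, volumetric removal
#' rate and net COD/N ratio.  Failures are captured per cycle and
#' reported without aborting the rest.  The summary table is written as
#' CSV and, with every stoichiometric constant used, as a
#' schema-versioned JSON report, so each number is reproducible from the
#' inputs and the logged constants alone.
#'
#' @param paths Character vector of cycle CSV files (or a directory, in
#'   which case all \code{*.csv} inside are used).
#' @param out_dir Output directory for \code{summary.csv} and
#'   \code{report.json}; \code{NULL} writes nothing.
#' @param constants A \code{stoich_constants} object.
#' @param nitrite_correction Passed to \code{\link{electron_balance}}.
#' @param cod_n_mode Passed to \code{\link{net_cod_n_ratio}}.
#' @param kinetics_method Passed to \code{\link{fit_first_order}}.
#' @return List with \code{summary} (data frame, one row per cycle),
#'   \code{balances}, \code{fits} and \code{errors}.
#' @export
run_pipeline <- function(paths, out_dir = NULL,
                         constants = stoich_constants(),
                         nitrite_correction = FALSE,
                         cod_n_mode = "residual",
                         kinetics_method = "log-linear") {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
  if (!length(paths)) stop("no input cycle files found")
  cycles <- list()
  for (p in paths) cycles <- c(cycles, read_cycle_csv(p))
  if (!length(cycles)) stop("no complete cycles found in the input files")

  rows <- list(); balances <- list(); fits <- list(); errors <- list()
  for (i in seq_along(cycles)) {
    res <- tryCatch({
      cy <- cycles[[i]]
      d <- cy$data
      bal <- suppressWarnings(
        electron_balance(cy, constants = constants,
                         nitrite_correction = nitrite_correction))
      n_removed <- d$no3n_mg_l[1] - d$no3n_mg_l[nrow(d)]
      fit <- NULL; rate <- c(mg_n_l_h = NA_real_, kg_n_m3_d = NA_real_)
      codn <- NA_real_
      if (n_removed > 0 && d$no3n_mg_l[1] > 0) {
        ok <- !is.na(d$no3n_mg_l)
        fit <- tryCatch(fit_first_order(d$time_h[ok], d$no3n_mg_l[ok],
                                        method = kinetics_method),
                        error = function(e) NULL)
        rate <- volumetric_removal_rate(
          d$no3n_mg_l[1], n_removed / d$no3n_mg_l[1],
          d$time_h[nrow(d)] - d$time_h[1])
        codn <- net_cod_n_ratio(cy, mode = cod_n_mode,
                                constants = constants, balance = bal)
      }
      list(bal = bal, fit = fit, rate = rate, codn = codn)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(i)]] <- conditionMessage(res)
      next
    }
    balances[[i]] <- res$bal; fits[[i]] <- res$fit
    rows[[i]] <- data.frame(
      cycle = i,
      c_t = res$bal$c_t, c_an = res$bal$c_an, c_de = res$bal$c_de,
      c_ot = res$bal$c_ot,
      ce_pct = res$bal$ce_pct, cce_pct = res$bal$cce_pct,
      frac_anode = res$bal$fractions[["anode_respiration"]],
      frac_denit = res$bal$fractions[["anodic_denitrification"]],
      frac_others = res$bal$fractions[["others"]],
      k_no3_h = if (is.null(res$fit)) NA_real_ else res$fit$k,
      removal_mg_n_l_h = res$rate[["mg_n_l_h"]],
      removal_kg_n_m3_d = res$rate[["kg_n_m3_d"]],
      net_cod_n = res$codn)
  }
  summary <- do.call(rbind, rows)
  bundle <- list(summary = summary, balances = balances, fits = fits,
                 errors = errors)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, na = "")
    report <- list(schema_version = "1.0",
                   constants = unclass(constants),
                   options = list(nitrite_correction = nitrite_correction,
                                  cod_n_mode = cod_n_mode,
                                  kinetics_method = kinetics_method),
                   cycles = summary,
                   errors = errors)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
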