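# Reporting surface: age-band aggregates (16-24 / 25-59 / 60+), relative
# changes over the projection window, state shares, and the two CSV report
# tables (caries; periodontal pocketing and loss of attachment) with
# point estimates in millions and interval bounds.

#' Default reporting age bands: 16--24, 25--59, 60+
#' @return Data frame with columns `age_lo`, `age_hi` (half-open).
#' @export
reporting_bands <- function() {
  data.frame(age_lo = c(16L, 25L, 60L), age_hi = c(25L, 60L, 101L))
}

.band_label <- function(age_lo, age_hi) {
  ifelse(age_hi >= 101L, paste0(age_lo, "+"), paste0(age_lo, "-", age_hi - 1L))
}

#' Aggregate a projected chain to reporting age bands
#'
#' Sums a state-tensor series over ages within each band and over sexes.
#' Bands must tile the adult range 16..100+ exactly.
#'
#' @param tensors List of `state_tensor`s (e.g. from [project_chain()]).
#' @param bands Data frame (`age_lo`, `age_hi`), default [reporting_bands()].
#' @return Long data frame: `year`, `band`, `age_lo`, `age_hi`, `state`,
#'   `count`.
#' @export
aggregate_age_bands <- function(tensors, bands = reporting_bands()) {
  bands <- bands[order(bands$age_lo), ]
  if (bands$age_lo[1L] != 16L || bands$age_hi[nrow(bands)] != 101L ||
      (nrow(bands) > 1L && any(bands$age_hi[-nrow(bands)] != bands$age_lo[-1L]))) {
    stopf("reporting bands must tile [16, 101) without gap or overlap")
  }
  out <- do.call(rbind, lapply(tensors, aggregate_to_bands,
                               bands = bands, by_sex = FALSE))
  out <- cbind(band = .band_label(out$age_lo, out$age_hi), out)
  rownames(out) <- NULL
  out[, c("year", "band", "age_lo", "age_hi", "state", "count")]
}

#' Relative change between two counts, in percent
#'
#' `100 * (v_end - v_start) / v_start`, rounded half-up to one decimal —
#' the "relative change 2020--2050" arithmetic of the report tables.
#'
#' @param v_start Baseline count (> 0).
#' @param v_end End-of-horizon count.
#' @return Percent change, one decimal.
#' @examples
#' relative_change(54.709, 58.356)  # 6.7
#' relative_change(4.278, 7.497)    # 75.2
#' @export
relative_change <- function(v_start, v_end) {
  if (any(v_start <= 0)) stopf("v_start must be > 0")
  round_half_up(100 * (v_end - v_start) / v_start, 1)
}

#' Share of a subgroup in a total, in percent
#'
#' `100 * part / whole`, rounded half-up to two decimals — the "share of the
#' burden carried by the 60+ population" arithmetic.
#'
#' @param part Subgroup count, `0 <= part <= whole`.
#' @param whole Total count (> 0).
#' @return Percent share, two decimals.
#' @examples
#' state_share(10.929, 25.751)  # 42.44
#' @export
state_share <- function(part, whole) {
  if (any(whole <= 0)) stopf("whole must be > 0")
  if (any(part < 0 | part > whole)) stopf("part must lie in [0, whole]")
  round_half_up(100 * part / whole, 2)
}

# Sum the output-table count over a cell (one chain, subset of states and
# bands, one year); for ensembles, per run.
.cell_total <- function(df, chain, states, age_lo, year, per_run = FALSE) {
  i <- df$chain == chain & df$state %in% states &
    df$age_lo %in% age_lo & df$year == year
  if (per_run) {
    v <- tapply(df$count[i], df$run[i], sum)
    as.numeric(v)
  } else {
    sum(df$count[i])
  }
}

# Format "x.xxx [lo-hi]" in millions (3 decimals, half-up).
.fmt_m <- function(point, lo = NA, hi = NA, persons_per_unit = 1e6) {
  p <- round_half_up(point / persons_per_unit, 3)
  if (is.na(lo)) return(sprintf("%.3f", p))
  sprintf("%.3f [%.3f-%.3f]", p,
          round_half_up(lo / persons_per_unit, 3),
          round_half_up(hi / persons_per_unit, 3))
}

# One report row across the three report years plus the relative change.
.report_row <- function(label, baseline, runs, chain, states, age_lo, years,
                        level = 0.95, persons_per_unit = 1e6) {
  a <- (1 - level) / 2
  cells <- character(length(years))
  for (j in seq_along(years)) {
    pt <- .cell_total(baseline, chain, states, age_lo, years[j])
    if (is.null(runs)) {
      cells[j] <- .fmt_m(pt, persons_per_unit = persons_per_unit)
    } else {
      rv <- .cell_total(runs, chain, states, age_lo, years[j], per_run = TRUE)
      cells[j] <- .fmt_m(pt, stats::quantile(rv, a, type = 7),
                         stats::quantile(rv, 1 - a, type = 7),
                         persons_per_unit = persons_per_unit)
    }
  }
  v0 <- .cell_total(baseline, chain, states, age_lo, years[1L])
  v1 <- .cell_total(baseline, chain, states, age_lo, years[length(years)])
  rc <- relative_change(v0, v1)
  if (is.null(runs)) {
    change <- sprintf("%.1f%%", rc)
  } else {
    r0 <- .cell_total(runs, chain, states, age_lo, years[1L], per_run = TRUE)
    r1 <- .cell_total(runs, chain, states, age_lo, years[length(years)], per_run = TRUE)
    ch <- 100 * (r1 - r0) / r0
    change <- sprintf("%.1f%% [%.1f-%.1f]", rc,
                      round_half_up(stats::quantile(ch, a, type = 7), 1),
                      round_half_up(stats::quantile(ch, 1 - a, type = 7), 1))
  }
  names(cells) <- paste0("y", years)
  c(list(row = label), as.list(cells), list(relative_change = change))
}

#' Emit the caries and periodontal report tables
#'
#' Builds the two report tables from a baseline output table (and, if an
#' ensemble is supplied, percentile interval bounds per cell and per-run
#' relative-change intervals): the caries table reports population, any
#' caries, untreated and treated caries by reporting age band; the
#' periodontal table reports any pocketing by band plus mild/moderate/severe
#' pocketing (4--<6, 6--<9, >=9 mm) and loss-of-attachment severities.
#' Counts are printed in millions to three decimals; band rows sum to the
#' Total row before rounding.
#'
#' @param baseline Output of [run_baseline()] aggregated to
#'   [reporting_bands()]; must contain chains `caries`, `pocketing`, `loa`.
#' @param runs Optional matching ensemble from [run_ensemble()].
#' @param out_dir Optional directory; if given, writes `table1_caries.csv`
#'   and `table2_periodontal.csv` there.
#' @param years The three report years (default 2020, 2035, 2050); all must
#'   be present in the tables.
#' @param level Interval coverage level for ensemble bounds.
#' @param persons_per_unit Persons per printed unit (default 1e6 = millions).
#' @return Invisibly, a list with data frames `caries` and `periodontal`.
#' @export
emit_tables <- function(baseline, runs = NULL, out_dir = NULL,
                        years = c(2020L, 2035L, 2050L), level = 0.95,
                        persons_per_unit = 1e6) {
  for (ch in c("caries", "pocketing", "loa")) {
    if (!ch %in% baseline$chain) stopf("baseline is missing chain '%s'", ch)
  }
  if (!all(years %in% baseline$year)) stopf("report years missing from baseline")
  if (!is.null(runs) && !all(years %in% runs$year)) stopf("report years missing from ensemble")
  bands <- unique(baseline[baseline$chain == "caries", c("age_lo", "age_hi")])
  bands <- bands[order(bands$age_lo), ]
  band_rows <- function(chain, states, section) {
    rows <- lapply(seq_len(nrow(bands)), function(b) {
      .report_row(.band_label(bands$age_lo[b], bands$age_hi[b]), baseline, runs,
                  chain, states, bands$age_lo[b], years, level, persons_per_unit)
    })
    rows[[length(rows) + 1L]] <- .report_row("Total", baseline, runs, chain,
                                             states, bands$age_lo, years,
                                             level, persons_per_unit)
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
    names(df) <- c("row", as.character(years), "relative_change")
    cbind(section = section, df)
  }
  total_row <- function(chain, states, label, section) {
    r <- .report_row(label, baseline, runs, chain, states, bands$age_lo, years,
                     level, persons_per_unit)
    df <- as.data.frame(r, check.names = FALSE)
    names(df) <- c("row", as.character(years), "relative_change")
    cbind(section = section, df)
  }

  cspec <- make_caries_spec()
  t1 <- rbind(
    band_rows("caries", cspec$states, "population"),
    band_rows("caries", c("untreated_caries", "treated_caries"), "caries"),
    band_rows("caries", "untreated_caries", "untreated_caries"),
    band_rows("caries", "treated_caries", "treated_caries")
  )

  pspec <- make_pocketing_spec()
  pocket_states <- pspec$states[-1L]
  t2 <- rbind(
    band_rows("pocketing", pocket_states, "periodontal_pocketing"),
    total_row("pocketing", "pocketing_4_6mm", "Mild pocketing", "pocketing_severity"),
    total_row("pocketing", "pocketing_6_9mm", "Moderate pocketing", "pocketing_severity"),
    total_row("pocketing", "pocketing_9mm_plus", "Severe pocketing", "pocketing_severity"),
    total_row("loa", "loa_4_6mm", "Mild LOA", "loa_severity"),
    total_row("loa", "loa_6_9mm", "Moderate LOA", "loa_severity"),
    total_row("loa", "loa_9mm_plus", "Severe LOA", "loa_severity"),
    total_row("loa", c("loa_4_6mm", "loa_6_9mm", "loa_9mm_plus"), "Total", "loa_severity")
  )
  rownames(t1) <- rownames(t2) <- NULL

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(t1, file.path(out_dir, "table1_caries.csv"), row.names = FALSE)
    utils::write.csv(t2, file.path(out_dir, "table2_periodontal.csv"), row.names = FALSE)
  }
  invisible(list(caries = t1, periodontal = t2))
}
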