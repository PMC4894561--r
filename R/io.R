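#' Plain-text artifact readers and writers
#'
#' All pipeline artifacts are CSV (curves, risk tables, interval counts,
#' pseudo-IPD, posterior draws, summary tables) or JSON (diagnostics,
#' run configuration).
#'
#' @name artifact-io
NULL

#' @rdname artifact-io
#' @param curve a [km_curve()] or data frame `time`, `survival`.
#' @param path file path.
#' @export
write_km_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_months = curve$time,
                              survival = curve$survival),
                   path, row.names = FALSE)
}

#' @rdname artifact-io
#' @export
read_km_csv <- function(path) {
  x <- utils::read.csv(path)
  km_curve(x$time_months, x$survival)
}

#' @rdname artifact-io
#' @param risk a [risk_table()] or data frame `time`, `n_at_risk`.
#' @export
write_risk_csv <- function(risk, path) {
  utils::write.csv(data.frame(time_months = risk$time,
                              n_at_risk = risk$n_at_risk),
                   path, row.names = FALSE)
}

#' @rdname artifact-io
#' @export
read_risk_csv <- function(path) {
  x <- utils::read.csv(path)
  risk_table(x$time_months, x$n_at_risk)
}

#' @rdname artifact-io
#' @param ipd a [pseudo_ipd()].
#' @export
write_ipd_csv <- function(ipd, path) {
  utils::write.csv(data.frame(time_months = ipd$time, event = ipd$event),
                   path, row.names = FALSE)
}

#' @rdname artifact-io
#' @param arm arm label to attach.
#' @export
read_ipd_csv <- function(path, arm = "") {
  x <- utils::read.csv(path)
  pseudo_ipd(x$time_months, x$event, arm)
}

#' @rdname artifact-io
#' @param intervals stacked interval-count rows (see [bin_monthly()]).
#' @export
write_intervals_csv <- function(intervals, path) {
  cols <- c("interval_start", "n_at_risk", "deaths", "censored",
            "arm", "study")
  out <- data.frame(interval_start = intervals$interval_start,
                    n_at_risk = intervals$n_at_risk,
                    deaths = intervals$deaths,
                    censored = intervals$censored,
                    arm = intervals$treatment,
                    study = intervals$study)
  utils::write.csv(out[cols], path, row.names = FALSE)
}

#' @rdname artifact-io
#' @export
read_intervals_csv <- function(path) {
  x <- utils::read.csv(path)
  data.frame(study = x$study, treatment = x$arm,
             interval_start = x$interval_start, n_at_risk = x$n_at_risk,
             deaths = x$deaths, censored = x$censored)
}

#' @rdname artifact-io
#' @param draws an [nma_fit()] result.
#' @export
write_draws_csv <- function(draws, path) {
  d <- draws$draws
  long <- do.call(rbind, lapply(seq_len(dim(d)[3]), function(ch) {
    m <- as.data.frame(d[, , ch])
    names(m) <- dimnames(d)[[2]]
    cbind(chain = ch, iteration = seq_len(nrow(m)), m)
  }))
  utils::write.csv(long, path, row.names = FALSE)
}

#' @rdname artifact-io
#' @param diagnostics an [nma_diagnostics()] result.
#' @export
write_diagnostics_json <- function(diagnostics, path) {
  jsonlite::write_json(diagnostics, path, auto_unbox = TRUE, digits = NA)
}
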