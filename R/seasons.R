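#' Classify study months into stratification seasons
#'
#' A month is de-stratified when the water column is mixed, operationally
#' when the surface-deep temperature difference is below `destrat_dT`
#' (default 1 degree C). Stratified months are assigned a fixed
#' calendar-determined phase: April-June is the beginning of the stratified
#' period, July-September the middle, and October-January the end. A
#' stratified February or March (not observed under the usual forcing, but
#' possible in an incomplete-mixing year) is assigned to the end phase,
#' contiguous with late winter.
#'
#' @param meta metadata data.frame (see [read_metadata()]); every month must
#'   carry a temperature for both layers.
#' @param destrat_dT mixing criterion in degrees C (strict `<`).
#' @return data.frame: month_index, year, calendar_month, label; one row per
#'   month, labels in {destratified, beginning, middle, end}.
#' @export
classify_seasons <- function(meta, destrat_dT = 1.0) {
  assert_scalar_num(destrat_dT, "destrat_dT", lower = 1e-12)
  months <- sort(unique(meta$month_index))
  out <- lapply(months, function(m) {
    sub <- meta[meta$month_index == m, ]
    ts <- sub$temperature_C[sub$layer == "surface"]
    td <- sub$temperature_C[sub$layer == "deep"]
    if (length(ts) != 1L || length(td) != 1L || anyNA(c(ts, td)))
      stop_("month_index %d: need one surface and one deep temperature", m)
    cal <- sub$calendar_month[1L]
    label <-
      if (abs(ts - td) < destrat_dT) "destratified"
      else if (cal %in% 4:6) "beginning"
      else if (cal %in% 7:9) "middle"
      else "end"                      # Oct-Jan, plus stratified Feb/Mar
    data.frame(month_index = m, year = sub$year[1L], calendar_month = cal,
               label = label)
  })
  do.call(rbind, out)
}

#' Months carrying a given season label
#' @param labels output of [classify_seasons()].
#' @param label one of `"destratified"`, `"beginning"`, `"middle"`, `"end"`.
#' @return integer vector of month indices (possibly empty).
#' @export
season_months <- function(labels,
                          label = c("destratified", "beginning", "middle", "end")) {
  label <- match.arg(label)
  if (is.null(labels) || nrow(labels) == 0L) return(integer())
  sort(labels$month_index[labels$label == label])
}
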