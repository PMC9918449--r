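#' Waterlogging yield loss (control vs waterlogged treatment)
#'
#' Percentage yield loss of a waterlogged treatment relative to its control:
#' `100 * (yield_ck - yield_wl) / yield_ck`. May be negative if the
#' waterlogged run out-yields the control.
#'
#' @param yield_ck Control yield, kg/ha (> 0).
#' @param yield_wl Waterlogged yield, kg/ha.
#' @return Yield loss, percent (`NA` with a warning where `yield_ck` is 0).
#' @examples
#' yield_loss_pct(1000, 800)  # 20
#' @export
yield_loss_pct <- function(yield_ck, yield_wl) {
  out <- 100 * (yield_ck - yield_wl) / yield_ck
  zero <- yield_ck == 0
  if (any(zero)) {
    warning("yield_ck = 0: loss undefined, returned NA")
    out[zero] <- NA_real_
  }
  out
}

#' Waterlogging yield penalty (default vs waterlogging-enabled model)
#'
#' Percentage yield difference between a simulation without waterlogging
#' physics (`yield_default`) and the waterlogging-enabled simulation on
#' identical inputs: `100 * (yield_default - yield_wl) / yield_default`.
#' Exactly 0 on seasons with no saturated days (model-equivalence).
#'
#' @param yield_default Yield from the default (no waterlogging physics)
#'   run, kg/ha (> 0).
#' @param yield_wl Yield from the waterlogging-enabled run, kg/ha.
#' @return Yield penalty, percent (`NA` with a warning where
#'   `yield_default` is 0).
#' @examples
#' yield_penalty_pct(2000, 1500)  # 25
#' @export
yield_penalty_pct <- function(yield_default, yield_wl) {
  out <- 100 * (yield_default - yield_wl) / yield_default
  zero <- yield_default == 0
  if (any(zero)) {
    warning("yield_default = 0: penalty undefined, returned NA")
    out[zero] <- NA_real_
  }
  out
}

#' Aggregate yield penalties per factorial cell
#'
#' Mean and median penalty across years/realisations for each combination of
#' the requested grouping columns.
#'
#' @param results A results table from [run_factorial()] (needs columns
#'   `yield_default`, `yield_wl` and the grouping columns).
#' @param by Character vector of grouping column names.
#' @return data.frame with per-group `n`, `mean_penalty`, `median_penalty`.
#' @export
aggregate_penalty <- function(results,
                              by = c("site", "genotype", "sowing_window",
                                     "scenario")) {
  pen <- yield_penalty_pct(results$yield_default, results$yield_wl)
  g <- interaction(results[by], drop = TRUE, sep = "|")
  rows <- lapply(split(seq_along(pen), g), function(ix) {
    cbind(results[ix[1], by, drop = FALSE],
          n = length(ix),
          mean_penalty = mean(pen[ix], na.rm = TRUE),
          median_penalty = stats::median(pen[ix], na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
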