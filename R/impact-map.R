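# Sliding-window relative-impact profile: the impact potential at position
# x is the mean impact code of all variants within x +/- half_window (30 bp
# by default); positions whose window holds no variant score 0.

#' Sliding-window impact profile along a region
#'
#' @param variant_impacts Data frame with columns `pos` and `impact`
#'   (impact codes 0-3, one number per variant -- typically the per-variant
#'   maximum, e.g. `ref_max_impact` or
#'   `pmax(ref_max_impact, alt_max_impact)` from [max_impact_table()]).
#' @param region Numeric length-2 vector `c(start, end)` (1-based
#'   inclusive) over which to evaluate the profile.
#' @param half_window Window half-width in nucleotides (default 30).
#' @return An `impact_profile` tibble with columns `pos` and `value`
#'   (raw mean impact, in `[0, 3]`), one row per region position.
#' @export
#' @examples
#' impact_profile(data.frame(pos = 100, impact = 3), c(1, 200))
impact_profile <- function(variant_impacts, region, half_window = 30L) {
  if (half_window < 0) abort("half_window must be >= 0")
  stopifnot(length(region) == 2L, region[1] <= region[2],
            all(variant_impacts$impact >= 0), all(variant_impacts$impact <= 3))
  xs <- seq.int(region[1], region[2])
  vi <- variant_impacts[order(variant_impacts$pos), , drop = FALSE]
  # prefix sums over the sorted variant positions: the window mean at x is
  # (S[hi] - S[lo]) / (hi - lo) with hi/lo from binary search
  csum <- c(0, cumsum(vi$impact))
  hi <- findInterval(xs + half_window, vi$pos)
  lo <- findInterval(xs - half_window - 0.5, vi$pos)
  cnt <- hi - lo
  val <- ifelse(cnt > 0, (csum[hi + 1L] - csum[lo + 1L]) / cnt, 0)
  structure(
    tibble(pos = xs, value = val),
    region = as.integer(region), half_window = as.integer(half_window),
    normalized = FALSE,
    class = c("impact_profile", "tbl_df", "tbl", "data.frame")
  )
}

#' Normalize an impact profile against reference profiles
#'
#' Scales every value of `target` by the maximum raw value observed across
#' the `references` (so a reference profile normalised against itself peaks
#' at exactly 1, and a target exceeding all references peaks above 1).  All
#' profiles must share region and half-window.
#'
#' @param target An [impact_profile()].
#' @param references List of [impact_profile()] objects (may include the
#'   target itself).
#' @return The target profile with `value` replaced by the normalised
#'   values and the raw values kept in `raw`.
#' @export
normalize_profiles <- function(target, references) {
  if (!is.list(references) || inherits(references, "impact_profile")) {
    references <- list(references)
  }
  for (r in references) {
    if (!identical(attr(r, "region"), attr(target, "region")) ||
        !identical(attr(r, "half_window"), attr(target, "half_window"))) {
      abort("target and reference profiles must share region and half_window")
    }
  }
  ref_max <- max(vapply(references, function(r) max(r$value), numeric(1)))
  if (ref_max <= 0) abort("all-zero reference profiles: scaling undefined")
  out <- target
  out$raw <- target$value
  out$value <- target$value / ref_max
  attr(out, "normalized") <- TRUE
  out
}

#' @export
print.impact_profile <- function(x, ...) {
  r <- attr(x, "region")
  cat(sprintf("<impact_profile> region %d-%d, half-window %d nt%s\n",
              r[1], r[2], attr(x, "half_window"),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  NextMethod()
}

#' Plot an impact profile
#'
#' @param object An [impact_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.impact_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_area(fill = "#2e7d32", alpha = 0.6) +
    ggplot2::labs(
      x = "position",
      y = if (isTRUE(attr(object, "normalized"))) "relative impact"
          else "mean impact (0-3)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
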