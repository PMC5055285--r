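#' Thermal-performance category scheme
#'
#' Defines an ordered set of body-temperature categories along a thermal
#' performance curve. The default is the seven-bin scheme for *Mytilus
#' californianus*: low lethal (< 0 °C), low sub-lethal (0–10), low sub-optimal
#' (10–17), optimal (17–22), high sub-optimal (22–32), high sub-lethal
#' (32–38) and high lethal (>= 38 °C). Bins are lower-inclusive and
#' upper-exclusive, so the boundary value 38 falls in the high-lethal bin.
#'
#' @param bounds Strictly increasing numeric thresholds in degrees Celsius;
#'   `length(bounds) + 1` categories tile the whole real line.
#' @param labels Character labels, one per category (ordered cold to hot).
#' @return An object of class `category_scheme` with elements `bounds`,
#'   `labels` and `k` (number of categories).
#' @examples
#' sch <- category_scheme()
#' categorize(c(-1, 18, 38.2), sch)
#' @export
category_scheme <- function(bounds = c(0, 10, 17, 22, 32, 38),
                            labels = c("low_lethal", "low_sublethal",
                                       "low_suboptimal", "optimal",
                                       "high_suboptimal", "high_sublethal",
                                       "high_lethal")) {
  if (!is.numeric(bounds) || anyNA(bounds) || is.unsorted(bounds, strictly = TRUE)) {
    stop("`bounds` must be strictly increasing finite thresholds")
  }
  if (length(labels) != length(bounds) + 1L) {
    stop("need exactly length(bounds) + 1 labels")
  }
  structure(list(bounds = as.numeric(bounds),
                 labels = as.character(labels),
                 k = length(bounds) + 1L),
            class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  lo <- c(-Inf, x$bounds)
  hi <- c(x$bounds, Inf)
  cat("Thermal-performance categories (lower-inclusive, upper-exclusive):\n")
  for (i in seq_len(x$k)) {
    cat(sprintf("  %d  %-16s [%s, %s) degC\n", i - 1L, x$labels[i], lo[i], hi[i]))
  }
  invisible(x)
}

#' Assign temperatures to thermal-performance categories
#'
#' @param temp Numeric body temperatures (degrees Celsius); must be finite.
#' @param scheme A [category_scheme()].
#' @return Integer category indices, 0-based (0 = coldest bin).
#' @export
categorize <- function(temp, scheme = category_scheme()) {
  stopifnot(inherits(scheme, "category_scheme"))
  if (anyNA(temp) || any(!is.finite(temp))) {
    stop("`temp` contains missing or non-finite values")
  }
  # findInterval gives bins [b_i, b_{i+1}) for default arguments
  findInterval(temp, scheme$bounds)
}
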