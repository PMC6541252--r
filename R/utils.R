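#' @keywords internal
#' @importFrom rlang .data
#' @importFrom tibble tibble
#' @importFrom dplyr bind_rows
"_PACKAGE"

# Shortest decimal representation that re-parses to exactly the same double.
# Descriptor files must preserve anchoring coordinates digit-for-digit across
# read/write cycles, and no stock formatter guarantees that.
fmt_double <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) stop("cannot serialize non-finite coordinate", call. = FALSE)
    if (xi == trunc(xi) && abs(xi) < 1e15) {
      return(sprintf("%.0f", xi))
    }
    for (d in 1:17) {
      s <- formatC(xi, digits = d, format = "g", width = -1)
      if (as.numeric(s) == xi) return(s)
    }
    sprintf("%.17g", xi)
  }, character(1))
}

# Round half up, componentwise (floor(x + 0.5)); base round() ties to even.
round_half_up <- function(x) floor(x + 0.5)

is_number3 <- function(x) is.numeric(x) && length(x) == 3L && all(is.finite(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
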