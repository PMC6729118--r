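# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; published percentage tables in this
#' domain use conventional half-up rounding (2.65 -> 2.7), so reporting code
#' routes through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Empty diagnostics table; all validation/IO reporting shares this shape.
empty_diagnostics <- function() {
  data.frame(
    level = character(), file = character(), item_id = character(),
    message = character(), stringsAsFactors = FALSE
  )
}

diagnostic <- function(level, message, file = NA_character_,
                       item_id = NA_character_) {
  data.frame(
    level = level, file = file, item_id = item_id, message = message,
    stringsAsFactors = FALSE
  )
}

bind_diagnostics <- function(...) {
  parts <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (length(parts) == 0) return(empty_diagnostics())
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable string fingerprint used in provenance records.
fingerprint <- function(x) digest::digest(x, algo = "sha256")
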