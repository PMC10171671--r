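#' Convert sodium (mg/day) to salt (g/day)
#'
#' Salt (g) = sodium (mg) x 2.5 / 1000. All internal risk-assessment
#' computation is in grams of salt per day; sodium mg appears only at the
#' I/O boundary.
#'
#' @param sodium_mg Non-negative numeric vector, sodium in mg/day.
#' @return Salt in g/day.
#' @examples
#' sodium_to_salt(2300) # 5.75
#' @export
sodium_to_salt <- function(sodium_mg) {
  stopifnot(is.numeric(sodium_mg))
  if (any(sodium_mg < 0, na.rm = TRUE)) {
    stop("sodium_mg must be non-negative", call. = FALSE)
  }
  sodium_mg * 2.5 / 1000
}

#' @rdname sodium_to_salt
#' @param salt_g Non-negative numeric vector, salt in g/day.
#' @export
salt_to_sodium <- function(salt_g) {
  stopifnot(is.numeric(salt_g))
  if (any(salt_g < 0, na.rm = TRUE)) {
    stop("salt_g must be non-negative", call. = FALSE)
  }
  salt_g * 1000 / 2.5
}
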